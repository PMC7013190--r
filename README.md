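# nfconn

Simulation and analysis of **connectivity-based real-time fMRI
neurofeedback** (rt-fMRI-nf). In this protocol, participants in the
scanner watch a 0–10 line gauge and try to move it upwards; the gauge
reflects the sliding-window (20 s) partial correlation between the
mean BOLD signals of two target regions — left DLPFC and bilateral
ACC — while a nuisance region absorbs global activation:

    r_DLPFC,ACC·noise = (r_xy − r_xz r_yz) / sqrt((1 − r_xz²)(1 − r_yz²))

The raw coefficient is scaled to gauge lines against each participant's
own localizer-calibrated connectivity range,

    NumberOfLines = (r − ConnectivityBaseline) /
                    (ConnectivityMax − ConnectivityBaseline) × 10,

rounded to the next integer and clamped to 0–10. Control participants
receive **yoked sham** feedback replayed from a matched experimental
participant.

`nfconn` is aimed at researchers who want to prototype, test or teach
this class of protocol without scanner data. It provides, as a tested
pipeline driven by a seeded synthetic BOLD generator:

* the experimental block designs (360 s localizer: 6 × 30 s Rest/Task;
  420 s neurofeedback runs: 6 × 25 s Rest / 45 s Regulate; TR = 1 s);
* a generator of ROI-mean BOLD time series with task-locked activation,
  condition-dependent target–target coupling, a shared global
  component, AR(1) noise and slow drift;
* localizer calibration (pool task-block windows, drop negatives,
  one mean ± 2 SD pass, min → ConnectivityBaseline, max →
  ConnectivityMax);
* a streaming per-TR feedback engine with batch replay and yoked sham;
* the offline neurofeedback-signal time course (percent change per run
  relative to localizer connectivity); and
* a simplified single-subject PPI model (OLS with a seed × Regulate
  interaction regressor) with a run-contrast helper, for parameter
  recovery on synthetic data.

## Worked example

Simulate a "responder" participant (coupling rising over runs 1–3,
dipping in run 4), calibrate from their localizer, and replay the
feedback engine:

```r
library(nfconn)

p   <- simulateParticipant("responder", seed = 42)
cal <- calibrate(p$localizer, makeLocalizerDesign())
cal
#> CalibrationResult: baseline 0.315, max 0.941 (60 retained; 0 negative, 6 outlier removed)
```

This participant's gauge maps windowed partial correlations of 0.315
and 0.941 to 0 and 10 lines. Feedback for run 1:

```r
nf <- makeNfDesign()
traces <- lapply(seq_along(p$nfRuns), function(r)
  runFeedback(p$nfRuns[[r]], nf, cal, runId = paste0("run", r)))
traces[[1]]
#> FeedbackTrace: 420 frames, veridical
#>   run run1; mean shown lines 4.52; 19 warm-up frames
```

The offline neurofeedback-signal time course, as percent change of each
run's mean Regulate-window connectivity relative to the localizer
reference (the mean retained calibration coefficient, 0.73 here):

```r
nfSignalTimecourse(traces, cal)
#>   runId meanRegulateR localizerRefR percentChange
#> 1  run1         0.547          0.73         -25.1
#> 2  run2         0.547          0.73         -25.0
#> 3  run3         0.627          0.73         -14.0
#> 4  run4         0.612          0.73         -16.2
```

The signal rises over runs 1–3 and dips at run 4, following the
responder's coupling schedule (percent change is negative because
regulate-block connectivity stays below the task-driven localizer
reference). The simplified first-level PPI for run 4, and the
run-1-vs-run-4 contrast of the seed × condition interaction:

```r
ppiFirstLevel(p$nfRuns[[4]], nf)
#> PpiResult (df = 416 , condition number = 23.23 )
#>               beta     se       t
#> intercept   2.6360 0.2521 10.4553
#> task        0.5168 0.0508 10.1791
#> seed        0.5336 0.0437 12.2141
#> interaction 0.0091 0.0543  0.1672
```

A single run-pair from a single synthetic subject is noisy; the
Monte Carlo tests in `tests/testthat/` show the interaction beta is
monotone in the simulated coupling modulation across seeds.

`endToEnd("responder", seed, outDir)` chains every stage (simulate →
calibrate → feedback → NF time course → PPI → contrast) and writes all
artifacts plus a machine-readable summary; a thin command-line wrapper
with the same stages as subcommands lives in `inst/scripts/nfconn`.
See the methods vignette (`vignettes/nfconn-methods.Rmd`) for the
generative model, parameter defaults and known limitations.

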