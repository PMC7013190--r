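---
title: "Methods: simulating connectivity-based real-time fMRI neurofeedback"
author: "nfconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating connectivity-based real-time fMRI neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfconn)
```

# The protocol

`nfconn` implements the computational core of a connectivity-based
real-time fMRI neurofeedback (rt-fMRI-nf) protocol. Participants view a
0--10 line gauge and try to raise it; the gauge reflects the
sliding-window partial correlation between the mean BOLD signals of two
target regions --- left DLPFC (fronto-parietal network) and bilateral
ACC (cingulo-opercular network) --- controlling for a nuisance region
that captures global activation. The protocol has two run types, both at
TR = 1 s:

* a **functional localizer** (incongruent Stroop): six 30 s Rest and six
  30 s Task blocks alternating, 360 volumes, used to calibrate each
  participant's feedback range; and
* four **neurofeedback runs**: six 25 s Rest and six 45 s Regulate
  blocks alternating, 420 volumes each, during which the gauge is
  displayed in Regulate blocks and updated every TR.

Both designs begin with a Rest block. The protocol description lists
Rest first for both run types and the feedback logic needs a
pre-regulate baseline, but the starting condition is not stated
explicitly anywhere; Rest-first is a convention of this package. Sample
indices are 0-based and a sample at time $t$ belongs to the block whose
half-open interval $[onset, onset + duration)$ contains it, so block
boundaries are never assigned twice. Brief instruction cues at block
starts are absorbed into the block durations: the published volume
counts (360, 420) are only consistent with whole-block accounting.

# The feedback signal

At every TR the engine computes the first-order partial correlation
over the most recent 20 samples (20 s at TR = 1 s; for other TRs the
window is `round(20 / trS)` samples to preserve the 20-second
semantics):

$$r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
  {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}$$

with Pearson correlations on mean-centred vectors; $x, y$ are the
target ROIs and $z$ the nuisance ROI. The pairwise formula is $O(n)$
per window; the test suite holds it against the residual-regression
definition (correlate the residuals of $x \sim z$ and $y \sim z$),
which is the mathematically primitive form.

Numerical conventions:

* If the nuisance channel has zero variance within a window, the
  coefficient reduces to the plain Pearson $r_{xy}$. This is exact, not
  a fallback: regressing on a constant removes only the mean, so the
  residual definition degenerates to Pearson. It also keeps noise-free
  simulations (where the nuisance channel is identically zero)
  well-defined.
* Zero variance in a target, or a nuisance perfectly collinear with a
  target, leaves the coefficient undefined: an `NA` marker inside
  windowed computation, an error when `partialCorr()` is called
  directly.
* Coefficients are clipped to $[-1, 1]$ to absorb floating-point
  overshoot.
* No within-window detrending is applied beyond the mean-centring
  implicit in Pearson correlation; the nuisance ROI carries the burden
  of removing global drift.

The raw coefficient is mapped to the gauge by

$$\mathrm{lines} = \frac{r - \mathrm{ConnectivityBaseline}}
  {\mathrm{ConnectivityMax} - \mathrm{ConnectivityBaseline}} \times 10,$$

rounded to the next integer and clamped (values $\ge 10$ display 10
lines, $\le 0$ display 0). "Next integer" is ambiguous between nearest
and ceiling; `nfconn` rounds half away from zero to the nearest
integer, isolated in one helper so the convention is swappable. The
sliding window uses the most recent 20 acquired TRs regardless of block
labels --- the display is merely hidden during Rest --- because the
gauge updates continuously every second and a per-block reset would
stall updates early in each Regulate block; whether the original
implementation reset per block is unknown. The first 19 frames of a run
are warm-up frames displaying 0 lines (deterministic and simplest;
holding a previous value would need an arbitrary initial value).

# Calibration

`calibrate()` derives the participant's feedback range from the
localizer: all full 20-sample windows lying entirely within Task blocks
(11 windows per 30 s block, 66 pooled) are computed, undefined windows
dropped, negative coefficients removed, then one mean $\pm$ 2 SD pass
(sample SD) removes outliers. The minimum and maximum retained
coefficients become ConnectivityBaseline and ConnectivityMax. Choices
where the protocol description is silent:

* negatives are removed **before** the 2 SD pass, matching the order in
  which the rules are stated, and the outlier pass runs once rather
  than iterating;
* windows are pooled across blocks (not summarised per block) before
  taking min/max;
* windows never straddle a Rest/Task boundary, the most literal reading
  of "extracted during task blocks".

The single-pass filter makes filtering idempotent by construction. When
calibration fails (empty or degenerate retained set),
`fallbackCalibration()` supplies the published group-mean range
(baseline 0.17, max 0.81) with a warning, mirroring the study's own use
of group-derived quantities when individual ones were unavailable.

# The synthetic BOLD generator

No imaging data were deposited for this protocol, so every stage is
exercised against a seeded generator (`simulateRun()`). Per sample $t$:

$$\mathrm{target}_i(t) = a\,x(t) + c(t)\,s(t) + g_a\,g(t) + d(t) + e_i(t),
\qquad
\mathrm{nuisance}(t) = g_a\,g(t) + d(t) + e_n(t)$$

* $x(t)$: the active-block boxcar convolved with a gamma HRF of mean
  lag 6 s and SD 3 s (shape 4, scale 1.5 s, unit-peak, support
  $[0, \mathrm{mean} + 5\,\mathrm{SD}]$), amplitude $a$ (`taskAmp`).
* $s(t)$: i.i.d. standard-normal shared latent whose loading $c(t)$ is
  `couplingRest` on Rest samples and `couplingRegulate` on active
  samples. Coupling acts through this shared component rather than by
  mixing the targets directly, which gives monotone control of the
  population partial correlation.
* $g(t)$: standard-normal series smoothed by the same HRF kernel and
  rescaled to unit variance (so `globalAmp` $g_a$ is the component's
  SD); the smoothing is computed with full-kernel overlap so the
  component is stationary from the first sample.
* $d(t)$: linear drift, `driftPerMin` units per minute.
* $e$: three independent stationary AR(1) processes (coefficient
  `ar1Phi`, innovation SD `noiseSd`).

Defaults are fixed once: `taskAmp` 1.0, `globalAmp` 0.8, `noiseSd` 1.0,
`ar1Phi` 0.3, `driftPerMin` 0.2. These are stand-ins --- the study never
characterises its signal or noise magnitudes --- chosen to be BOLD-like
(noise comparable to signal, mild autocorrelation, visible drift) and
documented as arbitrary. Coupling defaults are `couplingRest` 0.3 and
`couplingRegulate` 0.6; `simulateParticipant()` overrides them per
scenario: a *responder* follows the schedule 0.5, 0.7, 0.9, 0.8 over
runs 1--4 (learning over the first three runs with a final-run
fall-off, the qualitative shape reported for the protocol's
neurofeedback signal), a *non-responder* stays at the resting coupling.
The localizer uses a strong task coupling of 0.9 so that the calibrated
range is wide, as expected when an attentional-control task drives the
target pair.

All randomness flows from one seed through a documented sub-seeding
scheme (`subSeed()`): stream $k$ of seed $s$ is
$(31 (s \bmod M) + 131071 k) \bmod M$, $M = 2^{31} - 1$. Streams 1--5
of a run seed drive the shared latent, the global component and the
three noise processes; participant streams 100--104 derive the
localizer and run seeds. Identical inputs are bit-identical, and any
stream can be regenerated in isolation.

## What the generator does and does not emulate

It emulates task-locked activation, condition-dependent target-target
coupling, a shared global/nuisance component, temporally autocorrelated
noise and slow drift --- the features the analysis pipeline actually
consumes. It does not emulate voxel-level structure, motion,
physiological noise, spatial smoothing, scanner drift nonlinearity, or
inhomogeneous ROI sizes. Passing tests therefore show that the
*computations* behave as specified under a plausible signal model, not
that the protocol's empirical effect sizes would be recovered from real
scanner data.

One property of the model deserves emphasis: the nuisance channel is a
*noisy proxy* of the global component, so first-order partialling
under-corrects. Even with zero coupling, the mean windowed partial
correlation is well above zero at the default settings (the shared task
response, absent from the nuisance ROI, contributes too). The null of
"no shared signal at all" (task, global and coupling all zero) is
centred on zero, and that is the null the test suite asserts; the
partial-vs-raw gap growing with `globalAmp` is what demonstrates that
partialling works. In the real protocol the nuisance ROI averaged ~325
voxels and was therefore much less noisy than a single simulated
channel; readers should treat the absolute level of simulated
connectivity as arbitrary.

# Offline analyses

`nfSignalTimecourse()` expresses each run's mean defined post-warm-up
Regulate-window coefficient as percent change relative to localizer
connectivity. The localizer reference is the **mean** of the retained
calibration coefficients: the protocol says only "baseline connectivity
during the localizer task", and using ConnectivityBaseline (the
minimum) would make small changes look enormous.

`ppiFirstLevel()` is a deliberately simplified single-subject
psychophysiological interaction model: ordinary least squares of the
ACC series on an intercept, the HRF-convolved Regulate regressor, the
mean-centred DLPFC seed, and the interaction of the seed with a
zero-centred ($\pm 0.5$) Regulate/Rest boxcar. The interaction is
formed at the BOLD level (no deconvolution), matching the FEAT-style
construction; there is no prewhitening and there are no motion
regressors (the simulator generates no motion). `runContrast()`
differences the interaction betas of two runs with variance propagated
under an independent-runs assumption --- the single-subject analogue of
the study's run-1-vs-run-4 contrast. Group-level inference and
whole-brain maps are out of scope.

# Known limitations

* **Anticonservative PPI t-statistics.** The simulator's noise is
  autocorrelated (AR(1) plus the HRF-smoothed global component) and the
  PPI model deliberately applies no autocorrelation correction, so
  naive OLS standard errors are underestimated and the two-sided 5%
  rejection rate of the interaction t-test under a no-modulation null
  substantially exceeds its nominal band. The test suite measures
  exactly this; prewhitening (as FILM does in the full pipeline) would
  be required to restore nominal calibration and is intentionally not
  part of the simplified model.
* **Errors-in-variables attenuation.** The seed regressor contains
  measurement noise, which attenuates interaction estimates. The power
  check in the test suite therefore uses the strongest admissible
  modulation (`couplingRegulate` 1.5 vs `couplingRest` 0); weaker
  modulations are detected with correspondingly lower power.
* **Arbitrary magnitudes.** All simulator amplitudes are stand-ins, and
  the absolute simulated connectivity level reflects the noisy-proxy
  nuisance model (see above).

# Problem sizes

Monte Carlo checks in the test suite use 50 seeds per condition (500
for the null-calibration check, 200 for the pure-noise null, 30 for
secondary shape checks), sizes at which the asserted orderings are
stable under reseeding while the full suite completes in a few minutes
on one CPU. Oracle-equivalence checks use 1,000 random triples and 100
full runs.
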