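---
title: "Methods: dyadic blink coupling, NCR causality, and interbrain synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic blink coupling, NCR causality, and interbrain synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the tunable parameters, and the design
choices behind `blinksync` — in particular the choices that were genuinely
open and the reasons they were settled the way they were.

## The measurement chain

Eye-blinks are read off video as **motion energy**: for consecutive frames
the mean over ROI pixels of the absolute intensity difference. The value of
a frame pair is timestamped at the *later* frame, the instant at which the
motion is observable; this keeps downstream causal modeling honest (a blink
can never appear to precede its own physical evidence). Motion energy is
invariant to additive illumination shifts and absolutely homogeneous in
contrast, both of which are covered by tests.

Each 20 s condition block contributes only its final 15 s
(`analysis_window_s`), discarding the seconds around the condition switch
where brightness is unstable; at 30 Hz this gives 450 samples per block and
32 blocks per condition per participant in the canonical four-run design.
Each block sub-series is then linearly detrended (least-squares line
removal, which also zero-means the block). Detrending is per block, after
segmentation: trends are local artifacts of lighting drift, and fitting one
global line would leak between-block structure into the within-block
signal.

### Blink detection

Blinks are local maxima of the non-detrended motion-energy series whose
*topographic prominence* (height above the higher of the two saddles
toward taller terrain, with plateaus walked through) exceeds a threshold,
greedily thinned to a minimum separation — tallest first, earlier on exact
ties. Two defaults matter:

* `min_separation_s = 0.2` — the lower bound of the typical 200–400 ms
  blink duration; anything closer is one blink's internal structure, not
  two blinks.
* `min_prominence = 5 × raw MAD` of the block series. The original
  procedure verified detected peaks visually; an automatic, stated rule
  replaces that. The raw (unscaled) median absolute deviation is a robust
  noise scale that ignores the blink pulses themselves.

Blink *counting* uses the non-detrended series: blinks are positive
excursions, and removing a fitted line first could only move peaks around.

## The coupling model (Eqs. of the analysis)

Within each block the pair of detrended series is modeled as a bivariate
autoregression of order `N`,

$$x_t = \sum_{i=1}^{N} a_i x_{t-i} + \sum_{i=1}^{N} b_i y_{t-i} + u_{x,t},
\qquad
y_t = \sum_{i=1}^{N} c_i x_{t-i} + \sum_{i=1}^{N} d_i y_{t-i} + u_{y,t},$$

estimated by ordinary least squares on the joint regression — which is
identical to per-equation OLS and exactly checkable against a
normal-equations oracle (it is, at `1e-8`). No Yule–Walker moment
inversion is used. Residual variances use denominator `T − N`.

**Order selection.** `N` minimizes the multivariate Gaussian AIC,
`n log det(Σ̂) + 2(4N + 2)`, over orders 1–10, with all candidates
evaluated on the common sample `t = max_order+1, …, T` so their
likelihoods are comparable; ties go to the smallest order. Whether the
original analysis used joint or per-equation likelihood is unknowable from
the text; the joint Gaussian form is the standard choice for a jointly
estimated model. AIC overfits with a fixed asymptotic probability (the
χ² exceedance of its penalty); the tests therefore assert modal recovery
of a known order and absence of underfitting rather than a near-certain
hit rate.

**Transfer functions.** `H(f) = [I − Σ_k A_k e^{−2πifk/f_s}]^{−1}` is
evaluated by direct inversion of the 2×2 lag polynomial on a uniform grid
of `n_freqs = 513` points over `[0, f_s/2]`. This is mathematically the
Fourier transform of the impulse response without truncation error, and is
tested against a 2048-term truncated impulse-response FFT oracle at
`1e-6`. Unstable fits (companion spectral radius ≥ 1) are refused, and at
the participant level such blocks are skipped with a warning and excluded
from the across-block mean.

**NCR.** The noise contribution ratio uses the printed form with the
*marginal* residual variances,

$$\mathrm{NCR}_{y \to x}(f) =
\frac{|\beta(f)|^2 \sigma^2_{uy}}
     {|\alpha(f)|^2 \sigma^2_{ux} + |\beta(f)|^2 \sigma^2_{uy}},$$

which presumes near-independent innovations. Rather than silently
orthogonalizing, the fit reports the residual cross-correlation and warns
above |0.2|; fidelity to the published formula, with its assumption
surfaced. ΣNCR is the trapezoid integral over `[0, f_s/2]` (units Hz; 513
grid points make the trapezoid error negligible against estimation noise
for these smooth rational spectra). The four participant-level quantities
are face→face in LIVE, REPLAY and REST, plus screen→face in REPLAY, where
the screen series is the partner's own series shifted forward by the 20 s
video delay. Enhancement is the participant's condition value minus their
REST value.

## The synthetic dyad generator

No raw recordings accompany the original study and it describes no
generative model for blinks, so every simulator choice is this package's
own. The generator is a discrete-time thinning of a mutually exciting
point-process pair:

* baseline hazard `baseline_blink_rate / 60` (default 15 blinks/min, a
  typical spontaneous rate during attentive viewing);
* refractory period 0.4 s (at least the longest blink, 200–400 ms drawn
  uniformly per event);
* after each partner blink, the hazard is multiplied by
  `1 + gain · K(t − t_partner − latency)` where `K` is a raised-cosine
  kernel of width 0.5 s **normalized to unit time integral**. With that
  normalization each partner blink adds, in expectation,
  `gain × baseline hazard` reactive blinks, so the gain is directly
  interpretable and maps strongly and monotonically onto ΣNCR. A
  peak-normalized kernel was considered and rejected: at plausible gains
  it yields a reactive-blink fraction of a few percent, below what the
  downstream estimator can resolve at any reasonable simulation size, and
  the generator would not be able to demonstrate its own dial.
* coupling latency 0.25 s. A longer reactive latency (0.5 s) was
  considered and rejected for an identifiability reason one can state
  exactly: the analysis model sees at most `max_order / f_s = 0.33` s of
  history, so excitation centered beyond that horizon is invisible to the
  NCR by construction. 0.25 s is still a realistic reactive-blink
  latency and places the kernel inside the model's horizon.

When a schedule is supplied, the coupling is condition-gated by what each
participant can actually see: live partner blinks in LIVE, the partner's
blinks delayed by 20 s in REPLAY, nothing in REST. The response gain is
deliberately identical in LIVE and REPLAY — participants were told the
REPLAY video was live — so the conditions differ only in loop timing, not
reactivity. This reproduces the study's logic: a closed real-time loop
(LIVE) versus one-way delayed influence (REPLAY), where the delayed
influence is captured by the screen→face quantity and not by the
face→face one.

Blink *videos* are rendered as a darkening eyelid band sweeping down and
up over the ROI with lid velocity concentrated mid-blink (a `sin^6`
closure profile). The concentration is deliberate: motion energy is the
absolute derivative of lid position, so any smooth closure/reopening
yields two motion humps; concentrating the velocity keeps those humps
within the 0.2 s detector separation for all blink durations up to 0.4 s,
so one blink is detected as one event. Frames carry no sensor noise —
motion energy is exactly zero away from blinks, a tested invariant — while
the cheap scalar renderer (`events_to_motion_energy`) adds a half-normal
noise floor (`noise_sd = 0.5` intensity units against pulse height 10)
that keeps non-detrended values non-negative, like a real sensor's
rectified noise.

The voxel simulator produces, per voxel, `task_amp ×` (HRF-convolved
condition boxcars, identical in both participants) `+ √ρ · latent +
√(1−ρ) · noise` with the latent series shared within the pair, so the
task-free cross-correlation is `ρ` by construction and the task-locked
component is exactly the confound residualization must remove.

**What the generator does not emulate:** faces, gaze direction, partial
blinks or saccades, MRI physics (noise is white Gaussian), physiological
noise, motion artifacts, or spatial structure across voxels (voxels are
exchangeable and independent given the latent signal). Tests passing on
this generator show the *chain* is correct and calibrated — not that real
recordings meet its assumptions.

## Design bookkeeping

The printed per-block timings (20 s blocks, 1 s screen-off blank) cannot
tile the printed 510 s run for any integer number of rest blocks unless
the blank lives inside the block. The canonical schedule therefore is a
30 s initial REST settling block followed by 24 contiguous 20 s blocks
(8 LIVE, 8 REPLAY, 8 REST, pseudorandomized per run) with the 1 s blank
counted inside each block's final second; the final-15-s analysis window
never touches it. This preserves every printed constraint: 510 volumes
per run at TR 1 s, 32 sub-series per condition, 640 concatenated volumes
per face condition, and 2000 analyzed volumes per participant after
dropping 10 settling volumes per run. The initial settling block is
labeled REST but flagged `initial` and excluded from segmentation by
default, keeping REST at 32 sub-series like the other conditions.

## Inference layer

The repeated-measures ANOVA is a direct sums-of-squares decomposition
(one or two within factors with interaction), with **generalized η²** =
effect SS / (effect SS + subject SS + all error SS) — the
Olejnik–Algina/Bakeman definition appropriate for within designs — and
uncorrected degrees of freedom (no sphericity correction, matching the
reported df). It agrees with `aov()` error-strata output at `1e-8` in
tests. Post-hoc paired t tests use Bonferroni (`p_adj = min(1, m·p)`) and
pairwise within-subject confidence intervals computed from each pair's own
difference scores. The outlier rule is read the simplest way the text
allows: per condition across participants, candidate included, a
participant is dropped entirely if any of their condition values falls
outside mean ± 2 SD, and the ANOVA re-runs on the reduced sample.

## Interbrain synchronization

Residualization is per run: drop the first 10 volumes, then regress out
HRF-convolved boxcars for the non-REST conditions (REST is the implicit
baseline — including all three boxcars plus an intercept would be exactly
collinear), a run intercept, and a discrete-cosine high-pass basis with a
128 s cutoff. The HRF is the canonical double-gamma (gamma shapes 6 and
16, undershoot ratio 1/6, unit peak); the high-pass and HRF settings for
this stage are assumed to carry over from the activation GLM defaults, as
nothing in the synchronization subsection says otherwise. Volumes are
assigned to blocks by the half-open `[onset, onset + duration)` rule.
Spatial preprocessing being out of scope, "same template coordinates" is
modeled as shared abstract voxel ids. Pearson r is clamped to
±(1 − 1e-12) before `atanh`; zero-variance voxels get z = 0 with a
warning rather than an error, since a single dead voxel should not abort
a map.

## Problem sizes and numerical checks

The test suite and the acceptance script size their simulations for a
single CPU: gain-recovery uses 1200 s dyads summarized by the mean ΣNCR
over 150 s sub-blocks (the same averaging structure as the participant
summary, which is what makes the per-seed estimate stable), with common
random numbers across gain levels; directional asymmetry uses one long
fit per seed; null calibration uses 200 single-run dyads with a
199-permutation LIVE-vs-REST label test, and 3000 independent voxel pairs
at 640 volumes for the Fisher-z spread. Degenerate inputs are handled
explicitly: constant series refuse to fit (singular design), constant
blocks are skipped with a warning at the participant level, detection
refuses non-positive parameters, and the schedule constructor rejects
run-length mismatches.

## Known limitations

* The NCR uses marginal noise variances as printed; under strongly
  correlated innovations the two directional ratios are not a clean
  decomposition (the warning threshold is |r| > 0.2).
* AIC order selection overfits with fixed probability; ΣNCR inherits a
  small positive bias (visible as the nonzero null floor), which is why
  condition comparisons are always within-participant differences.
* The 20 s REPLAY delay exceeds the AR horizon, so face→face REPLAY
  influence is structurally invisible to the model — that is the point of
  the screen→face quantity, and simulations here reproduce it.
* Cluster-level family-wise inference for the voxel contrast is out of
  scope; the paired t map reports uncorrected p values.
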