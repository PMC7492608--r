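---
title: "Methods: PMBR dynamics and learner grouping in a real-world motor task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMBR dynamics and learner grouping in a real-world motor task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

When people learn a motor skill, the transient increase in 13–30 Hz
(beta-band) EEG power that follows the end of each voluntary movement — the
post-movement beta rebound (PMBR) — carries a signature of the learning
mechanism in play. In constrained laboratory tasks the PMBR *increases*
over learning when errors drive adaptation (it correlates negatively with
movement error) and *decreases* when learning is reward-driven. In an
unconstrained, real-world skill task (repeated billiards shots at a fixed
target pocket), both patterns can coexist in the same cohort: some subjects
behave like error-based learners (PMBR increasers, negative PMBR–error
correlation) and others like reward-based learners (PMBR decreasers,
positive correlation).

`pmbr` implements the full analysis chain for this question — directional
shot errors from ball tracking, per-trial PMBR from single-channel EEG over
the contralateral motor cortex, data-driven bimodal grouping of subjects,
and behavioral skill-learning metrics — together with a synthetic-cohort
generator that emulates the statistical structure the analysis assumes.
Because the original raw recordings are not deposited in a public archive,
every quantitative claim the package makes is established by
parameter-recovery tests on the calibrated synthetic world, not by
reproducing subject-level values.

## The analysis pipeline

**Tracking.** The cue-ball movement onset is the first video frame at which
the ball centre leaves a 40 × 40 mm bounding box centred on its initial
position (ball diameter 48 mm). The target ball's movement angle is taken
from its position at peak speed relative to its start, measured against the
cue-start-to-target-start line; the signed directional error is that angle
minus the pocket angle, wrapped to (−180°, 180°], counterclockwise
positive. Speeds are central finite differences after a 5-sample
(25 ms at 200 Hz) moving average; the smoothing choice is ours — the study protocol
leaves it unspecified — and ties in peak speed break to the
earliest sample. The 300 trials per subject segment into 6 sets of 50 and
12 analysis blocks of 25.

**Spectral analysis.** Epochs are band-pass filtered at 5–35 Hz (zero-phase
Hamming windowed-sinc, 385 taps; designed in-package because no FIR-design
package is available in the target environment) and decomposed with complex
Morlet wavelets in 1 Hz steps. The wavelet width is fixed at 7 cycles for
all frequencies (temporal SD ≈ 56 ms at 20 Hz, envelope support ±4 SD);
samples within half a wavelet of an epoch edge are flagged invalid and
never enter any window. Power is converted to percent change relative to
the block average by the literal log-then-normalize reading:
per frequency row, `value = 100·(ln P / ⟨ln P⟩_block − 1)`, where the block
mean runs over all valid samples of all trials in the block. The
alternative order (block-average the raw power, then log-ratio) is
available behind `norm_method = "log_ratio"`; the protocol wording
supports the first reading, and the switch documents the
ambiguity. Normalization is computed per frequency row (the field
convention for percent-change maps) and over trial epochs only — the
synthetic world has no inter-trial recording. Note two consequences of the
log transform: the percent scale depends on the absolute power units (a
global rescaling of the recording changes values; the extracted *dynamics*
are invariant, which is what the tests assert), and the block mean of
`ln P` must be positive — the generator's amplitude scales guarantee this,
and the code refuses to divide by a near-zero mean.

**PMBR extraction.** Movement offset is proxied by the ball-movement onset
(the best-defined event in a self-paced task; any follow-through lies well
inside the window). The band-averaged (13–30 Hz) normalized power is
searched over the 2 s after offset; the PMBR is the mean over a 200 ms
window centred on the peak, truncated (and flagged) at the search-window
boundaries, ties to the earliest sample. Peak search operates on the
band-averaged series, not per-frequency peaks. A baseline beta value (mean
over 500 ms ending 100 ms before onset) is reported for the
group-baseline control; the study protocol defines no baseline window,
so this one is an addition for reporting symmetry. Per-trial PMBR values
are averaged over blocks.

**Behavioral metrics.** Learning rate is
`(E_first − E_plateau)/E_first` with `E_first` the mean absolute error over
trials 1–25 and `E_plateau` over trials 201–300. Intertrial variability is
the per-block sample SD (n−1) of signed errors; its decay is first-block SD
minus pooled-plateau SD. Trial-to-trial change is the mean |Δ error| over
within-block consecutive pairs (block boundaries are not spanned — a
documented choice). ACF(1) is the Pearson correlation of consecutive
signed errors computed over session halves (150 trials each), not blocks,
because short-series autocorrelation estimates are biased; signed (not
absolute) errors carry the error-correction structure. Manipulative
complexity of a joint-velocity matrix is the normalized eigenvalue entropy
of its sample covariance, `C = −Σ λ̂ᵢ ln λ̂ᵢ / ln N`: C = 1 when all
principal components contribute equally, C = 0 when one dominates. The
cited complexity measure is not restated in the study protocol; this form
satisfies both printed endpoint properties and is flagged as our concrete
choice.

**Grouping.** The subject-level statistic is the Pearson correlation
between the 12 block PMBR values and the 12 block mean absolute errors.
Gaussian mixtures of 1–5 components are fitted by EM (diagonal
covariances, k-means++ initialization, 10 restarts, tolerance 1e-6) and
scored with AIC and AICc; AICc with a non-positive correction denominator
is +Inf and never selected. Degenerate EM runs — a vanishing component
weight, or a variance collapsing onto a few points (component SD below 5%
of the data SD) — are restarted: the unequal-variance mixture likelihood
is unbounded at such spike solutions, and a best-of-restarts rule would
otherwise actively select them, biasing the information criteria toward
spurious extra components. The 5% cutoff sits at the lower edge of a wide
insensitive region (selection behaviour is flat between 5% and 10%), well
below the tightest genuine cluster scale in any fixture (≈10%). Diagonal covariance is forced because a full
12-dimensional covariance is unidentifiable at n = 30 — for the
12-dimensional block-PMBR matrix every multi-component AICc is undefined,
so that analysis reads AIC. Fuzzy c-means (fuzzifier m = 2, tolerance
1e-6, ≤1000 iterations, 10 restarts) over 2–10 clusters is validated with
a within/between ratio index,
`Σ_k Σ_i u_ik^m ‖x_i − v_k‖² / (n · min_{j≠k} ‖v_j − v_k‖²)` (smaller is
better); the cited index is described only qualitatively in the study
protocol, so
the contract asserted in tests is the ratio form, smaller-better, minimum
at the true count. Group labels come from the two-component posterior,
with a sign-purity check and a warned sign-based fallback. Trend fits and
group comparisons use ordinary `lm()`/`t.test()` — routine statistics are
delegated, not reimplemented.

## The synthetic world

The generator's defaults *are* the stated study conditions: 30 subjects
(16 negative-coupling, 14 positive-coupling), 300 trials, 256 Hz
single-channel EEG, 200 Hz tracking.

* **Errors.** `e_t = μ_t + x_t` with exponentially decaying bias and
  marginal SD and an AR(1) innovation schedule that reproduces the SD
  schedule exactly. Group defaults were calibrated once — closed-form
  folded-normal means plus a Monte-Carlo correction for the small Jensen
  bias of the realized learning-rate ratio — so the expected learning
  rates equal the reported 0.48 (increasers) and 0.60 (decreasers):
  increasers 7.02° → 2° bias, 5° → 3.5° SD, τ = 50 trials, ρ = 0.25;
  decreasers 10.56° → 1.5°, 9° → 3.5°, τ = 20, ρ = 0.30. The decreaser
  group's larger initial variability, faster decay and larger early
  trial-to-trial changes, and the increaser group's higher complexity
  targets (0.55→0.70 vs 0.45→0.62), encode the reported qualitative
  behavioral contrasts.
* **Coupling.** Each subject's true PMBR–error correlation is drawn from
  the reported group distributions, N(−0.40, 0.26) or N(+0.47, 0.17),
  truncated at zero to preserve the group sign. Block PMBR values are
  `base + scale·(ρ·z(E_b) + √(1−ρ²)·η_b)` (base 40%, scale 8%), with the
  noise vector η residualized against the standardized errors so the
  *sample* correlation over the 12 blocks equals ρ exactly. The reported
  distributions describe fitted correlations; adding independent noise
  instead would convolve them with 12-point resampling error (SD ≈ 0.25),
  inflating the group spreads to ≈ 0.36 and pulling the expected count of
  negative-correlation subjects down to ≈ 14.9 of 30 — measurably
  inconsistent with the reported 16/14 split.
* **EEG.** 6-s epochs with movement offset at 3 s (trial durations in a
  self-paced task are unconstrained; 6 s leaves the full 2-s search window plus
  margins on both sides). Traces are 1/f background + 13–30 Hz baseline
  activity with a Gaussian desynchronization dip ending at offset + a
  Gaussian-envelope 20 Hz burst (envelope SD 150 ms, centre 0.35–0.75 s
  after offset). The burst amplitude for a programmed PMBR target comes
  from a calibration sweep: amplitudes on a fixed grid are pushed through
  the *actual* extraction path once (under a private fixed seed, cached),
  and the monotone mean mapping is inverted by interpolation. Peak-picking
  over 2 s of noisy band power has a floor of ≈20% at zero amplitude (at
  the default SNR); the programmed base of 40% puts block values in the
  responsive range of this mapping.
* **Kinematics and head movement.** Joint velocities are latent components
  with a geometric eigenvalue profile whose decay ratio is solved by
  bisection against the sample-covariance complexity (tolerance 0.005,
  clamped at the achievable ends). Head-acceleration traces carry a
  movement bump whose magnitude is independent of the PMBR, matching the
  null control.

What a green test does **not** establish: the synthetic EEG has no
artifacts (blinks, EMG, electrode noise), one channel, no volume
conduction, and a single stereotyped burst per trial, so the pipeline's
robustness to real-world contamination is untested by design; ICA/artifact
rejection is deliberately out of scope. Exact subject-level values of the
original study are not reproducible without the raw data.

## Numerical and design notes

* Because the programmed sample correlation is exact, sign flips in the
  recovered labels can come only from extraction noise acting on subjects
  whose |ρ| is very small; the expected number per default cohort is a
  fraction of a subject, so the 16/14 sign split and near-perfect label
  recovery are reproducible. The noise-free round trip (strong coupling,
  clean EEG) recovers labels exactly.
* Multi-seed recovery runs analyse only the 13–30 Hz rows: because
  normalization is per frequency row, every beta-band output is bit-for-bit
  identical to the 5–35 Hz run (a test asserts this); it is purely a
  compute-scaling device.
* EDF I/O is implemented in-package (16-bit, 1-s records) because the
  target environment ships no EDF reader; round-trip error is one
  quantization step of the physical range.
* Degenerate inputs: zero-variance trend fits return F = 0; constant
  correlation inputs return NA; blocks with no usable trials fail loudly
  naming the block; AICc guards, EM restarts on vanishing components and
  FCM reinitialization on coincident centers are all exercised in tests.
* Cohorts with fewer than 5 subjects skip mixture/cluster selection and
  fall back to sign-based labels (smoke-test path).
* The `pipeline_cli` surface is the exported `run_pipeline()` /
  `make_report()` pair plus the thin `inst/cli/pmbr-pipeline.R` wrapper;
  configs serialize to YAML and runs are cached per stage with a manifest.

* The fuzzy-cluster validity index is implemented in its stated
  within/between ratio form. On 30 one-dimensional correlations this form
  prefers many tiny clusters sitting on chance clumps in roughly 15% of
  simulated cohorts (the min-separation denominator shrinks more slowly
  than the within term); on clearly bimodal cohorts it selects two. This
  is a property of the index family, reported as measured rather than
  patched with a large-c penalty, which would break the index's documented
  monotone response to cluster separation.

## Known limitations

The burst-amplitude calibration is specific to the sampling rate, epoch
geometry and SNR it was run for (it is cached per parameter set); the
percent-change scale inherits the non-scale-invariance of the log
normalization; and the generator's group contrasts are programmed, so
behavioral-contrast tests validate the *pipeline's ability to detect* the
contrasts, not their empirical existence.
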