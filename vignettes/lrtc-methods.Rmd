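---
title: "Measuring long-range temporal correlations in EEG amplitude envelopes"
author: "lrtcpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring long-range temporal correlations in EEG amplitude envelopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrtcpipe)
```

## The measurement problem

Resting-state cortical oscillations are not memoryless: the amplitude
envelope of a band-limited rhythm (alpha, 8–13 Hz, being the canonical
case) fluctuates with a slowly decaying autocorrelation that extends over
seconds to minutes. This *long-range temporal correlation* (LRTC) is
quantified by detrended fluctuation analysis (DFA): a scaling exponent of
0.5 indicates an uncorrelated envelope, values in (0.5, 1] increasingly
persistent fluctuations. Individual differences in the envelope exponent
(written DFAe below) have been related to behavioural and psychological
measures of temporal consistency; this package implements the full chain
from cleaned multi-channel recordings to those individual-difference
statistics, together with a synthetic-data generator that provides ground
truth for every stage.

The pipeline stages are:

1. **Epoching** — overlapping 20-s epochs on a fixed grid, with
   boundary-aware rejection and subject-inclusion bookkeeping.
2. **Envelope DFA** — zero-phase FIR band-pass, Hilbert envelope,
   fluctuation function over 26 log-linear window sizes (1–20 s), slope
   fit over 2–16 s.
3. **Surrogate null** — amplitude-adjusted Fourier transform (AAFT)
   surrogates of the band-filtered epochs, yielding a cohort-level
   critical value for the exponent.
4. **Reliability** — split-half ICC(1,k) over non-overlapping epochs.
5. **Questionnaires** — EPSI identity synthesis/confusion and CES-D
   scoring with Cronbach's alpha.
6. **Association** — Spearman partial rank correlations between DFAe and
   identity scores with a fixed covariate set, one-tailed
   Bonferroni-adjusted inference, and a descriptive band × channel map.

## The DFA variant implemented

For each epoch the band-limited amplitude envelope is mean-centered and
cumulatively summed into a profile. For each window size $t$ the profile
is tiled with non-overlapping windows from the first sample (partial tail
windows are discarded), each window is linearly detrended by least
squares, and the SD of the detrended samples is recorded. The
fluctuation function is

$$F(t) = \langle \mathrm{SD}_w(t) \rangle_{w,\ \mathrm{epochs}},$$

the *mean of per-window SDs* pooled across all epochs — not the
root-mean-square aggregation of canonical DFA. The mean-of-SDs form is
the measurement this pipeline standardizes on; the canonical RMS variant
is available behind `method = "rms"` in `fluctuation_function()`. For
power-law inputs the two differ only in the intercept, not the slope.

DFAe is the ordinary-least-squares slope of $\log_{10} F$ against
$\log_{10} t$ restricted to the closed range 2–16 s. With the default
26 log-linear sizes between 1 and 20 s, 18 sizes fall in the fit range.
Scales beyond 16 s are deliberately out of scope: a 20-s epoch contains a
single 20-s window, so larger scales cannot be estimated from this epoch
length.

Numerical details that are choices rather than mathematics:

* The envelope is mean-centered before cumulative summation. Per-window
  detrending makes the fitted slope insensitive to this, but it fixes
  the profile definition.
* Window sizes round to integer samples half-away-from-zero; duplicate
  sizes after rounding collapse with a warning.
* The epoch grid is anchored at the first sample; windows tile from the
  profile's first sample.
* The per-window SD uses the sample (n − 1) denominator; at the smallest
  fitted window (500 samples at 250 Hz) the distinction from the
  population denominator is a 0.1% intercept effect and no slope effect.
* Internally the per-window residual sums of squares are computed from
  cumulative moments with two exact stabilisations (each window is
  referenced to its bracketing secant line, and each profile is globally
  linearly detrended first — both leave the detrended residuals
  unchanged); this keeps the fast path within 1e−12 of a naive
  per-window loop even on adversarial inputs.

## Filtering and envelope extraction

Band-pass extraction uses a linear-phase FIR filter (Hamming-window
design, order 62) applied zero-phase, i.e. with the symmetric
forward–backward kernel, evaluated as a true linear convolution on a
zero-padded FFT. Order 62 is the published choice for the alpha band;
the same order is retained for theta (4–8), beta (13–30) and gamma
(30–45 Hz), whose orders the source analyses do not state. At 250 Hz
this filter passes 10 Hz at gain 0.996 and suppresses 2 Hz to 0.017
(single pass). The envelope is the magnitude of the analytic signal,
computed on the same zero-padded transform; no edge trimming is applied
within an epoch, so the envelope tapers over roughly a quarter second at
each epoch edge. These are documented choices: trimming and single-pass
filtering were considered and rejected to keep every epoch's envelope
the same length as the epoch.

## The AAFT surrogate null

An AAFT surrogate (i) reorders sorted Gaussian deviates by the rank
order of the input, (ii) randomizes the phases of that Gaussian series
(each positive-frequency coefficient rotated by an independent uniform
phase, Hermitian symmetry kept, DC and Nyquist untouched — so the
Gaussian periodogram is preserved exactly), and (iii) reorders the
input's sorted values by the rank order of the phase-randomized series.
The output has exactly the input's value multiset and approximately its
spectrum.

Two points matter for interpreting the null:

* **What AAFT destroys.** The *direct* DFA slope of a series is a
  second-order (spectral) property and therefore survives surrogacy.
  What does not survive is the LRTC of the *envelope* of an oscillation:
  envelope memory lives in the phase organisation that step (ii)
  randomizes. The surrogate test is accordingly a test of the envelope
  exponent, and the package's property tests check exactly that
  (surrogate DFAe falls below the original on envelope-modulated
  signals, while the direct slope of a bare fGn series is retained).
* **The surrogate floor is above 0.5.** The envelope of narrow-band
  noise is itself smooth on the ~0.2-s scale set by the filter
  bandwidth, which lifts the fitted 2–16 s slope above the white-noise
  value. On simulated 8–13 Hz noise cohorts the pipeline's surrogate
  grand mean sits near 0.58 and the upper-1% critical value of
  per-iteration cohort means near 0.59 (30 subjects × 100 iterations;
  `surrogate_floor_simulation()` recomputes this). Observed exponents
  must clear this floor, not 0.5, to indicate genuine LRTC.

Surrogacy is applied to the band-filtered per-epoch series (the
band-limited signal is the object whose envelope is analysed), and the
surrogate then runs through the *unchanged* standard path — including
the band-pass filter. Re-filtering matters: the rank-remapping of step
(iii) leaks a little power outside the band, and passing surrogates
through the same filter as the originals keeps null and observed
measurements comparable. Both decisions are exposed as arguments
(`prefilter`, `refilter`) with the defaults above. Within an ensemble,
iteration $i$ uses a seed derived from the master seed and $i$; epochs
consume sequential draws from that iteration's stream, so runs are
exactly reproducible.

The critical value uses the linear-interpolation empirical quantile
(`stats::quantile` type 7) of the per-iteration cohort means, at the
upper 1% by default. Study-scale ensembles (2000 iterations) are
supported; simulations in the test suite use 100–200.

## The synthetic-data generator

Real recordings give no access to the true envelope exponent, so
validation uses constructed signals: a **carrier** (white Gaussian noise
passed through the pipeline's own band-pass) multiplied by a strictly
positive **modulator** $\exp(\sigma z(t))$, where $z$ is standardized
fractional Gaussian noise (fGn) with Hurst parameter equal to the target
exponent, generated exactly by Davies–Harte circulant embedding.

Two generator parameters were fixed once, by calibration, and are not
meant to be tuned per run:

* **Envelope rate, 5 Hz.** The modulator must survive the band-pass: a
  modulator with spectral content beyond the filter's ~2.5 Hz
  half-bandwidth is partially destroyed (biasing recovery down), while a
  modulator sampled too slowly leaves the smallest fitted window with
  only a handful of modulator values and interpolation smoothness
  inflates the slope (biasing up). 5 Hz — fGn Nyquist equal to the
  half-bandwidth — balances the two, leaving ≥ 10 modulator samples in
  the 2-s window.
* **Modulation depth, σ = 0.55.** Depth trades off two biases: a shallow
  modulator is swamped by the carrier's own envelope fluctuations at
  high target exponents; a deep one amplifies the lognormal distortion
  and the null-floor elevation at low targets. A calibration grid over
  σ ∈ {0.45, 0.55, 0.65} × H ∈ {0.55, 0.65, 0.75, 0.85} (20 seeds each,
  300-s signals) gave worst-case mean recovery errors of 0.088, 0.066
  and 0.099; σ = 0.55 was frozen.

With these defaults the mean recovered exponent is within 0.08 of the
target across H ∈ [0.55, 0.85]. At the uncorrelated end the generator
shows the same floor as the surrogate analysis: H = 0.5 signals measure
at 0.61 ± 0.03, elevated by the narrow-band carrier. This is a property
of the *measurement*, shared by any finite-bandwidth envelope analysis,
and is why the surrogate null — not the nominal 0.5 — is the reference
for real data.

The **cohort generator** draws per-subject exponents uniformly on
[0.55, 0.95] through a Gaussian copula linking four latent traits
(exponent, identity confusion, identity synthesis, depressive tendency).
Latent Spearman targets are converted to Pearson correlations via
$r = 2\sin(\pi\rho/6)$; the fixed questionnaire inter-correlations
(confusion–synthesis −0.56, confusion–depression 0.54,
synthesis–depression −0.51) emulate the published scale behaviour, and
the exponent–confusion correlation is the user's dial. Items are noisy
Likert discretizations of the latent traits (EPSI 1–5, CES-D 0–3 with
the standard four reverse-keyed items stored in raw form), so scale
scores are exactly sums of items. Discretization attenuates the
exponent–confusion correlation by a few percent at the default item
noise — the generator hits its nominal target only up to that
attenuation, which the tests account for. Covariates (age 18–36, 0/1
gender, BMI ~ N(21, 2.5²) truncated, arousal 1–9) are plausible but
deliberately uninformative. The generator makes no attempt at
biophysical realism: no 1/f background, no artifacts, no cross-channel
structure. Passing recovery tests therefore shows the *estimator chain*
is correct, not that real EEG satisfies the generative model.

## Epoching and inclusion bookkeeping

Epochs are 20 s with 75% overlap (5-s grid step) anchored at the first
sample; any candidate epoch containing an upstream splice boundary is
dropped. Subjects are excluded when fewer than 10 epochs remain
(strictly fewer — exactly 10 is included), when flagged non-compliant,
or when questionnaire data are missing, with that fixed precedence so a
subject is counted in exactly one category. The precedence and the
sample-0 grid anchor are not dictated by the measurement and are fixed
here for reproducible reports.

## Reliability and questionnaire scoring

Split-half reliability selects the maximal set of non-overlapping
epochs greedily from the first (every 4th epoch on the 75% grid), takes
equal-sized first and last halves (an odd middle epoch is dropped),
computes DFAe per half, and reports the one-way random-effects,
absolute-agreement, average-measures ICC(1,k) with its F-based 95%
confidence interval. Zero between-subject variance is reported as
ICC = 0 with a degeneracy flag rather than a negative estimate.

EPSI identity synthesis and confusion are 6-item sums (1–5 responses,
range 6–30, no reverse-coding — the subscales are scored separately
because synthesis and confusion coexist rather than being opposite
poles). CES-D is the standard 20-item sum (0–3 responses) with items 4,
8, 12, 16 reverse-scored; the item→subscale key and reverse list ship
as editable CSVs under `inst/extdata/` since instrument versions vary.
Cronbach's alpha uses sample (n − 1) variances.

## Association analysis and inference

All association tests are Spearman partial rank correlations: every
variable (gender coded 0/1) is rank-transformed with average ranks, and
the partial correlation of the ranked focal pair given the ranked
controls is computed by residual regression (an inverse-correlation-
matrix route is provided and tested to agree to 1e−10). The control set
is age, gender, BMI, arousal, retained epoch count, plus the respective
other identity factor; the CES-D score can be appended as a sensitivity
analysis. Controls that are constant across the analysed subjects are
dropped with a message (they carry no confounding information and would
make the rank regression singular); incomplete rows are dropped listwise
and counted.

The two focal tests (exponent vs synthesis, positive; exponent vs
confusion, negative) are one-tailed by design, with Bonferroni
adjustment over m = 2. p-values use the t approximation with
n − 2 − k degrees of freedom. The one-sided 95% confidence bound uses
the Fisher z transform with standard error $1/\sqrt{n - k - 3}$ — a
documented choice; the source analyses name no CI method, so no claim
of exact replication of printed bounds is made. The descriptive band ×
channel map reports unadjusted two-sided partial correlations with
two-sided Fisher-z intervals, and `descriptive_extrema()` labels the
strongest positive synthesis and strongest negative confusion entries
(ties broken lexicographically by band then channel).

Under null cohorts the familywise one-tailed Bonferroni-adjusted
rejection rate at the 0.05 level is calibrated (binomially consistent
with 5% across 200 simulated cohorts in the test suite).

## Problem sizes used by the test suite

The packaged simulations are sized to be informative rather than
study-scale: the surrogate-floor run uses 30 subjects × 100 iterations
of 300-s signals; parameter recovery uses 20 seeds per target exponent;
inference calibration uses 200 null cohorts of 68 subjects; reliability
and smoke tests use 5–10 subjects. Study-scale settings (68 subjects,
2000 iterations, 63 channels) run through the same code paths
unchanged.

## Known limitations

* The fit range stops at 16 s; slower LRTC is invisible by design.
* The mean-of-SDs aggregation, sample-0 anchors, and filter-order reuse
  across bands are fixed conventions where the underlying measurement
  literature is silent; each has a config toggle or documented default.
* The generator's exponent recovery is bias-calibrated only on
  [0.55, 0.95] at 300 s / 250 Hz in the alpha band; other regimes
  require re-calibration.
* Artifact rejection (bad channels, bursts, ICA) is upstream and out of
  scope: the pipeline expects cleaned signals plus splice-boundary
  indices.
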