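# lrtcpipe

Long-range temporal correlations (LRTC) in the amplitude envelopes of
band-limited EEG rhythms, and their relation to individual-difference
measures.

Resting-state oscillations such as the 8–13 Hz alpha rhythm have
amplitude envelopes whose autocorrelation decays slowly over seconds to
minutes. Detrended fluctuation analysis (DFA) summarizes this as a
scaling exponent ("DFAe"): 0.5 for a memoryless envelope, values in
(0.5, 1] for increasingly persistent fluctuations. `lrtcpipe` implements
the full analysis chain used in individual-differences EEG work of this
kind:

* **Epoching** of cleaned continuous recordings into 20-s epochs with
  75% overlap, boundary-aware rejection, and subject-inclusion
  bookkeeping (minimum epoch counts, compliance flags, missing
  questionnaires).
* **Envelope DFA**: order-62 zero-phase FIR band-pass (theta/alpha/
  beta/gamma), Hilbert envelope, fluctuation function `F(t)` over 26
  log-linear window sizes from 1 to 20 s computed as the mean of
  per-window detrended SDs, and the exponent as the log–log slope over
  2–16 s.
* **AAFT surrogate null**: amplitude-adjusted Fourier transform
  surrogates of the band-filtered epochs, per-subject surrogate-exponent
  ensembles, and the cohort-level upper-percentile critical value.
* **Reliability**: split-half DFAe agreement via the one-way
  random-effects, absolute-agreement, average-measures ICC(1,k).
* **Questionnaires**: EPSI identity synthesis/confusion (6 + 6 items,
  1–5) and CES-D (20 items, 0–3, four reverse-keyed) scoring plus
  Cronbach's alpha.
* **Association**: Spearman partial rank correlations between DFAe and
  identity scores controlling for age, gender, BMI, arousal, retained
  epoch count and the other identity factor, with one-tailed
  Bonferroni-adjusted p-values, one-sided Fisher-z bounds, and a
  descriptive band × channel correlation map.
* **Synthetic data**: exact fractional-Gaussian-noise simulation
  (Davies–Harte), band-limited oscillations with a controllable
  envelope exponent, and questionnaire cohorts with a Gaussian-copula
  link between the true exponent and identity-confusion scores — ground
  truth for every stage.

The statistic at the core is the fluctuation function of the
cumulative-summed envelope,

    F(t) = < SD of linearly detrended profile windows of length t >,

with DFAe the OLS slope of log10 F(t) vs log10 t for t in [2, 16] s.

## Worked example

One synthetic subject with a strongly persistent envelope
(true exponent 0.85), measured and tested against its surrogate null:

```r
library(lrtcpipe)

sim    <- generate_modulated_oscillation(signal_spec(envelope_exponent = 0.85,
                                                     seed = 7))
epochs <- segment_epochs(sim$signal, fs = 250, subject_id = "S001")
epochs
#> <epoch_set> 57 epochs of 20 s at 250 Hz; 1 channel(s)

dfa_per_subject(epochs, "alpha")
#>   subject_id channel  band      dfae intercept n_epochs fit_window_count
#> 1       S001     ch1 alpha 0.7847634  0.525847       57               18

surrogate_dfae_ensemble(epochs, "alpha", n_iterations = 50, seed = 1)
#> <surrogate_ensemble> S001 ch1 alpha : 50 iterations;
#>   mean surrogate DFAe 0.596 (original 0.7848)
```

The measured exponent (0.78) recovers the ground truth to within the
generator's calibrated bias, and surrogacy — which preserves the
signal's value distribution and spectrum but destroys envelope memory —
drops it to the measurement floor near 0.6, confirming the original
value reflects genuine temporal structure.

Questionnaire scoring and the focal inference machinery are equally
direct:

```r
score_epsi(c(5, 4, 4, 3, 2, 5,  1, 2, 2, 3, 1, 2))
#> synthesis confusion
#>        23        11

one_tailed_inference(-0.27, n = 68, controls_count = 6,
                     direction = "negative", m = 2)[c("p_adjusted", "ci_bound")]
#> $p_adjusted
#> [1] 0.03381208
#> $ci_bound
#> [1] -0.06264
```

An end-to-end run over a synthetic cohort — epoching, DFA, surrogates,
reliability, scoring, association — is one call:

```r
res <- run_pipeline(default_config(seed = 1, n_subjects = 10), "out/run1")
```

which writes `epochs_manifest.csv`, `exclusion_report.json`, `dfae.csv`,
`surrogate_subjects.csv`, `surrogate_cohort.json`, `reliability.json`,
`scores.csv`, `association_focal.csv`, `association_map.csv` and
`summary.json` (stamped with a config hash) to the run directory.

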