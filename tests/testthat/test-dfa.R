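test_that("envelope of a 10 Hz unit sinusoid is flat at one", {
  fs <- 250
  t <- seq_len(20 * fs) / fs
  env <- bandpass_envelope(sin(2 * pi * 10 * t), fs, "alpha")
  central <- env[seq(0.1 * length(env), 0.9 * length(env))]
  expect_true(all(abs(central - 1) < 0.02))
})

test_that("stop-band tones are suppressed", {
  fs <- 250
  t <- seq_len(20 * fs) / fs
  env <- bandpass_envelope(sin(2 * pi * 2 * t), fs, "alpha")
  central <- env[seq(0.1 * length(env), 0.9 * length(env))]
  expect_lt(mean(central), 0.05)
})

test_that("a known amplitude modulator is recovered by the envelope", {
  fs <- 250
  t <- seq_len(20 * fs) / fs
  m <- 1 + 0.5 * sin(2 * pi * 0.3 * t)
  env <- bandpass_envelope(m * sin(2 * pi * 10.5 * t), fs, "alpha")
  idx <- seq(0.1 * length(env), 0.9 * length(env))
  expect_lt(sqrt(mean((env[idx] - m[idx])^2)) / sqrt(mean(m[idx]^2)), 0.03)
})

test_that("band edges at or beyond Nyquist are rejected", {
  expect_error(bandpass_envelope(rnorm(5000), 250, c(30, 125)), "Nyquist")
  expect_error(bandpass_envelope(rnorm(100), 250, "alpha"), "too short")
})

test_that("window sizes follow the log-linear formula", {
  s <- make_window_sizes(1, 20, 26, 250)
  expect_length(s, 26)
  expect_equal(s[1], 250L)
  expect_equal(s[26], 5000L)
  expected <- as.integer(sign(x <- 250 * 20^((0:25) / 25)) * floor(abs(x) + 0.5))
  expect_equal(s, expected)
  expect_true(all(diff(s) > 0))
  expect_equal(make_window_sizes(1, 4, 3, 10), c(10L, 20L, 40L))
  expect_warning(make_window_sizes(1, 1.02, 5, 100), "collapsed")
})

test_that("fluctuation function matches the naive per-window oracle", {
  set.seed(31)
  cases <- list(
    list(env = list(rnorm(1000)), sizes = c(10L, 37L, 250L, 1000L)),
    list(env = lapply(1:4, function(i) rnorm(800) * 10^i),
         sizes = c(13L, 100L, 400L)),
    list(env = list(cumsum(rnorm(1200))), sizes = c(25L, 300L)))
  for (cs in cases) {
    ff <- fluctuation_function(cs$env, cs$sizes, fs = 100)
    expect_lt(max(abs(ff$F - oracle_fluctuation(cs$env, cs$sizes)) / ff$F),
              1e-10)
    ffr <- fluctuation_function(cs$env, cs$sizes, fs = 100, method = "rms")
    expect_lt(max(abs(ffr$F - oracle_fluctuation(cs$env, cs$sizes, "rms")) /
                    ffr$F), 1e-10)
  }
})

test_that("window bookkeeping: exact tiling counts and tail discard", {
  ff <- fluctuation_function(rnorm(1000), c(250L, 300L, 1000L), fs = 100)
  expect_equal(ff$n_windows, c(4L, 3L, 1L))
})

test_that("white-noise 'envelopes' give a DFA slope near 0.5", {
  set.seed(7)
  envs <- lapply(1:50, function(i) rnorm(5000))
  ff <- fluctuation_function(envs, make_window_sizes(1, 20, 26, 250), 250)
  est <- fit_exponent(ff)
  expect_lt(abs(est$exponent - 0.5), 0.05)
  # F grows with window size for these inputs
  expect_true(all(diff(ff$F) > 0))
})

test_that("an exact power law is fitted to machine precision", {
  sizes <- make_window_sizes(1, 20, 26, 250)
  ff <- structure(list(sizes_samples = sizes, sizes_s = sizes / 250,
                       F = 3.7 * (sizes / 250)^0.73,
                       n_windows = rep(1L, 26), fs = 250, method = "sd",
                       degenerate = FALSE),
                  class = "fluctuation_function")
  est <- fit_exponent(ff)
  expect_equal(est$exponent, 0.73, tolerance = 1e-12)
  expect_equal(est$fit_window_count, 18)
})

test_that("degenerate and under-determined inputs are refused", {
  expect_warning(ff <- fluctuation_function(rep(1, 500), c(10L, 50L), 100),
                 "constant")
  expect_true(ff$degenerate)
  expect_error(fit_exponent(ff), "degenerate")
  ff2 <- fluctuation_function(rnorm(500), c(10L, 50L), 100)
  expect_error(fit_exponent(ff2), "fewer than 3")
})

test_that("DFA exponent is invariant under positive rescaling", {
  es <- fixture_noise_epochs()
  d1 <- dfa_per_subject(es, "alpha")
  es2 <- es
  es2$epochs <- lapply(es$epochs, function(e) 1e4 * e)
  d2 <- dfa_per_subject(es2, "alpha")
  expect_equal(d1$dfae, d2$dfae, tolerance = 1e-12)
})

test_that("per-subject table has one row per channel-band combination", {
  es <- fixture_noise_epochs()
  d <- dfa_per_subject(es, "alpha")
  expect_equal(nrow(d), 1)
  expect_named(d, c("subject_id", "channel", "band", "dfae", "intercept",
                    "n_epochs", "fit_window_count"))
  d4 <- dfa_per_subject(es, canonical_bands())
  expect_equal(nrow(d4), 4)
  expect_setequal(d4$band, c("theta", "alpha", "beta", "gamma"))
})

test_that("channel processing order does not affect values", {
  sig <- cbind(A = generate_bandlimited_noise(60, 250, c(8, 13), seed = 1),
               B = generate_bandlimited_noise(60, 250, c(8, 13), seed = 2))
  es_ab <- segment_epochs(sig, 250, subject_id = "s")
  es_ba <- segment_epochs(sig[, c("B", "A")], 250, subject_id = "s")
  d_ab <- dfa_per_subject(es_ab, "alpha")
  d_ba <- dfa_per_subject(es_ba, "alpha")
  expect_equal(d_ab$dfae[d_ab$channel == "A"], d_ba$dfae[d_ba$channel == "A"])
  expect_equal(d_ab$dfae[d_ab$channel == "B"], d_ba$dfae[d_ba$channel == "B"])
})

test_that("estimated exponents track ground truth across a small cohort", {
  hs <- seq(0.6, 0.9, length.out = 12)
  est <- sapply(seq_along(hs), function(i) {
    sim <- generate_modulated_oscillation(
      signal_spec(duration_s = 120, envelope_exponent = hs[i],
                  seed = 500 + i))
    dfa_per_subject(segment_epochs(sim$signal, 250, subject_id = "s"),
                    "alpha")$dfae
  })
  expect_gt(cor(hs, est, method = "spearman"), 0.8)
})
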