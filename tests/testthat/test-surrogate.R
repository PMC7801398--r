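test_that("AAFT output is a permutation of the input, exactly", {
  set.seed(1)
  for (s in 1:5) {
    x <- rnorm(1000)
    y <- aaft_surrogate(x, seed = s)
    expect_identical(sort(y), sort(x))
  }
  x4 <- c(1, 2, 3, 4)
  expect_setequal(aaft_surrogate(x4, seed = 1), x4)
})

test_that("AAFT is deterministic given a seed; constant input warns", {
  x <- rnorm(256)
  expect_identical(aaft_surrogate(x, seed = 3), aaft_surrogate(x, seed = 3))
  expect_false(identical(aaft_surrogate(x, seed = 3),
                         aaft_surrogate(x, seed = 4)))
  expect_warning(y <- aaft_surrogate(rep(2, 100), seed = 1), "constant")
  expect_identical(y, rep(2, 100))
  expect_error(aaft_surrogate(c(1, 2), seed = 1), "length at least 4")
})

test_that("phase randomization preserves the Gaussian periodogram", {
  x <- cumsum(rnorm(512))
  d <- aaft_surrogate(x, seed = 5, details = TRUE)
  pg <- function(v) Mod(fft(v))^2
  p1 <- pg(d$gaussian)
  p2 <- pg(d$phase_randomized)
  expect_lt(max(abs(p1 - p2) / pmax(p1, 1e-12)), 1e-8)
})

test_that("surrogacy preserves the spectrum but destroys envelope LRTC", {
  # the direct DFA slope of a series is a spectral property, which AAFT
  # keeps; the envelope exponent of an oscillation is not, and falls
  sizes <- make_window_sizes(1, 16, 20, 250)
  slope_of <- function(v) {
    fit_exponent(fluctuation_function(v, sizes, 250))$exponent
  }
  direct <- t(sapply(1:10, function(s) {
    x <- generate_fgn(0.9, 4096, seed = 700 + s)
    c(orig = slope_of(x), sur = slope_of(aaft_surrogate(x, seed = s)))
  }))
  expect_lt(abs(mean(direct[, "sur"]) - mean(direct[, "orig"])), 0.1)

  wins <- sapply(1:30, function(s) {
    sim <- generate_modulated_oscillation(
      signal_spec(duration_s = 60, envelope_exponent = 0.9, seed = 700 + s))
    es <- segment_epochs(sim$signal, 250, subject_id = "s")
    en <- surrogate_dfae_ensemble(es, "alpha", n_iterations = 1, seed = s)
    en$surrogate_dfae[1] < en$original_dfae
  })
  expect_gte(mean(wins), 0.9)
})

test_that("ensemble runs are reproducible and flatten LRTC subjects", {
  es <- fixture_lrtc_epochs()
  e1 <- surrogate_dfae_ensemble(es, "alpha", n_iterations = 1, seed = 11)
  e2 <- surrogate_dfae_ensemble(es, "alpha", n_iterations = 1, seed = 11)
  expect_identical(e1$surrogate_dfae, e2$surrogate_dfae)

  e <- surrogate_dfae_ensemble(es, "alpha", n_iterations = 30, seed = 12)
  expect_lt(e$per_subject_mean, e$original_dfae)
  expect_equal(e$per_subject_mean, mean(e$surrogate_dfae))
})

test_that("surrogates of band-limited noise keep its exponent level", {
  es <- fixture_noise_epochs()
  e <- surrogate_dfae_ensemble(es, "alpha", n_iterations = 30, seed = 13)
  expect_lt(abs(e$per_subject_mean - e$original_dfae), 0.05)
})

test_that("cohort critical value: degenerate and toy cases", {
  mk <- function(v) structure(list(surrogate_dfae = v,
                                   per_subject_mean = mean(v),
                                   n_iterations = length(v)),
                              class = "surrogate_ensemble")
  cs <- cohort_critical_value(list(mk(rep(0.5, 4)), mk(rep(0.5, 4))))
  expect_equal(cs$critical_value, 0.5)
  cs2 <- cohort_critical_value(list(mk(c(0.5, 0.6, 0.7)),
                                    mk(c(0.7, 0.6, 0.5))))
  expect_equal(cs2$per_iteration_cohort_means, rep(0.6, 3))
  expect_equal(cs2$critical_value, 0.6)
  expect_error(cohort_critical_value(list(mk(c(0.5, 0.6)), mk(0.5))),
               "mismatched")
  expect_error(cohort_critical_value(list(mk(c(0.5, 0.6)))), "at least 2")
})

test_that("percentile convention is the linear-interpolation quantile", {
  mk <- function(v) structure(list(surrogate_dfae = v,
                                   per_subject_mean = mean(v),
                                   n_iterations = length(v)),
                              class = "surrogate_ensemble")
  v <- seq(0.4, 0.8, length.out = 101)
  cs <- cohort_critical_value(list(mk(v), mk(v)), percentile = 0.99)
  expect_equal(cs$critical_value, unname(quantile(v, 0.99, type = 7)))
})
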