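test_that("partial correlation with no controls is plain Spearman", {
  set.seed(51)
  x <- rnorm(40); y <- x + rnorm(40)
  sp <- spearman_partial(x, y)
  expect_equal(sp$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  expect_equal(sp$p_two_tailed,
               cor.test(x, y, method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("y = x gives rho = 1 even with controls", {
  set.seed(52)
  x <- rnorm(30)
  Z <- matrix(rnorm(60), 30, 2)
  expect_equal(spearman_partial(x, x, Z)$rho, 1, tolerance = 1e-10)
})

test_that("residual and inverse-matrix routes agree with the oracle", {
  set.seed(53)
  for (i in 1:5) {
    x <- rnorm(30); y <- rnorm(30)
    Z <- matrix(rnorm(150), 30, 5)
    r1 <- spearman_partial(x, y, Z, method = "residuals")$rho
    r2 <- spearman_partial(x, y, Z, method = "invcor")$rho
    r3 <- oracle_partial_spearman(x, y, Z)
    expect_lt(abs(r1 - r2), 1e-10)
    expect_lt(abs(r1 - r3), 1e-10)
  }
})

test_that("rho is invariant under strictly increasing transforms", {
  set.seed(54)
  x <- runif(30); y <- runif(30); Z <- matrix(rnorm(60), 30, 2)
  r0 <- spearman_partial(x, y, Z)$rho
  expect_equal(spearman_partial(exp(3 * x), y, Z)$rho, r0, tolerance = 1e-12)
  expect_equal(spearman_partial(x, y^3, Z)$rho, r0, tolerance = 1e-12)
})

test_that("constant variables are refused by name", {
  x <- rnorm(20)
  expect_error(spearman_partial(x, rep(1, 20)), "constant after ranking: y")
  Z <- cbind(age = rep(30, 20))
  expect_error(spearman_partial(x, rnorm(20), Z), "age")
})

test_that("one-tailed inference behaves at the reference points", {
  inf0 <- one_tailed_inference(0, 68, 6, "negative")
  expect_equal(inf0$p_one_tailed, 0.5)
  expect_equal(inf0$p_adjusted, 1.0)
  # effect opposite to the hypothesized direction
  expect_gt(one_tailed_inference(0.3, 68, 6, "negative")$p_one_tailed, 0.5)
  expect_gt(one_tailed_inference(-0.3, 68, 6, "positive")$p_one_tailed, 0.5)
  # the focal negative-correlation configuration is significant at 0.05
  inf <- one_tailed_inference(-0.27, 68, 6, "negative", m = 2)
  expect_gt(inf$p_adjusted, 0)
  expect_lte(inf$p_adjusted, 0.05)
  expect_equal(round(inf$p_adjusted, 1), 0.0)
  expect_lt(inf$ci_bound, 0)       # one-sided upper bound below zero
  expect_equal(inf$ci_side, "upper")
})

test_that("the full analysis detects a latent negative correlation", {
  hits <- sapply(1:50, function(s) {
    co <- generate_cohort(cohort_spec(n_subjects = 68,
                                      latent_confusion_correlation = -0.3,
                                      seed = 3000 + s),
                          generate_signals = FALSE)
    sc <- score_epsi(co$questionnaire)
    subjects <- data.frame(co$covariates,
                           epsi_synthesis = sc$synthesis,
                           epsi_confusion = sc$confusion,
                           cesd = score_cesd(co$questionnaire))
    dfae_table <- data.frame(subject_id = co$truth$subject_id,
                             channel = "FCz", band = "alpha",
                             dfae = co$truth$envelope_exponent,
                             n_epochs = sample(10:57, 68, replace = TRUE))
    res <- dfae_identity_analysis(dfae_table, subjects)
    res$focal$rho[res$focal$y_label == "confusion"] < 0
  })
  expect_gte(mean(hits), 0.9)
})

test_that("surrogate-mean exponents carry no identity correlation", {
  co <- generate_cohort(cohort_spec(n_subjects = 68,
                                    latent_confusion_correlation = -0.5,
                                    seed = 61),
                        generate_signals = FALSE)
  sc <- score_epsi(co$questionnaire)
  subjects <- data.frame(co$covariates,
                         epsi_synthesis = sc$synthesis,
                         epsi_confusion = sc$confusion)
  # stand-in for per-subject surrogate means: exponent structure destroyed
  surrogate_like <- local({
    set.seed(62)
    0.56 + 0.01 * rnorm(68)
  })
  dfae_table <- data.frame(subject_id = co$truth$subject_id,
                           channel = "FCz", band = "alpha",
                           dfae = surrogate_like,
                           n_epochs = rep(c(20L, 30L, 40L, 50L), 17))
  res <- dfae_identity_analysis(dfae_table, subjects)
  expect_true(all(res$focal$p_adjusted > 0.05))
})

test_that("descriptive extrema pick the right cells with tie rule", {
  map <- data.frame(band = c("theta", "theta", "beta", "beta"),
                    channel = c("Fp2", "CP3", "Fp2", "CP3"),
                    y = c("synthesis", "synthesis", "confusion", "confusion"),
                    rho = c(0.34, 0.1, -0.1, -0.33),
                    p_two_tailed = 0.1, ci_low = 0, ci_high = 0, n = 68)
  ex <- descriptive_extrema(map)
  expect_equal(ex$max_synthesis$rho, 0.34)
  expect_equal(ex$max_synthesis$channel, "Fp2")
  expect_equal(ex$min_confusion$rho, -0.33)
  expect_equal(ex$min_confusion$channel, "CP3")
  # ties resolve lexicographically by (band, channel)
  map$rho <- c(0.3, 0.3, -0.2, -0.2)
  ex2 <- descriptive_extrema(map)
  expect_equal(ex2$max_synthesis$band, "theta")
  expect_equal(ex2$max_synthesis$channel, "CP3")
  single <- map[1, ]
  ex3 <- descriptive_extrema(single)
  expect_equal(ex3$max_synthesis$rho, 0.3)
  expect_null(ex3$min_confusion)
})

test_that("listwise deletion drops and reports incomplete rows", {
  co <- generate_cohort(cohort_spec(n_subjects = 30, seed = 63),
                        generate_signals = FALSE)
  sc <- score_epsi(co$questionnaire)
  subjects <- data.frame(co$covariates,
                         epsi_synthesis = sc$synthesis,
                         epsi_confusion = sc$confusion)
  subjects$bmi[3] <- NA
  dfae_table <- data.frame(subject_id = co$truth$subject_id,
                           channel = "FCz", band = "alpha",
                           dfae = co$truth$envelope_exponent,
                           n_epochs = rep(c(20L, 30L, 57L), 10))
  expect_message(res <- dfae_identity_analysis(dfae_table, subjects),
                 "dropped listwise")
  expect_equal(res$n_dropped, 1)
  expect_equal(res$focal$n[1], 29)
})
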