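# Independent reference implementations used as oracles. Deliberately
# naive (explicit loops, textbook formulas, stats::aov / lm fits): they
# share no code with the production paths they check.

# Local Whittle estimator of the Hurst parameter from the periodogram.
oracle_whittle_H <- function(x, m = floor(length(x)^0.65)) {
  n <- length(x)
  I <- Mod(fft(x - mean(x)))^2 / (2 * pi * n)
  lambda <- 2 * pi * (1:m) / n
  Ij <- I[2:(m + 1)]
  obj <- function(H) {
    g <- lambda^(2 * H - 1)
    log(mean(Ij * g)) - (2 * H - 1) * mean(log(lambda))
  }
  stats::optimize(obj, c(0.01, 0.99))$minimum
}

# Naive fluctuation function: explicit per-window loops and lm() fits.
oracle_fluctuation <- function(envelopes, sizes, method = "sd") {
  if (is.numeric(envelopes) && is.null(dim(envelopes))) {
    envelopes <- list(envelopes)
  }
  sapply(sizes, function(s) {
    sds <- c()
    for (e in envelopes) {
      y <- cumsum(e - mean(e))
      nw <- length(y) %/% s
      for (w in seq_len(nw)) {
        seg <- y[((w - 1) * s + 1):(w * s)]
        tt <- seq_len(s)
        r <- stats::resid(stats::lm(seg ~ tt))
        sds <- c(sds, if (method == "sd") stats::sd(r) else
          sqrt(sum(r^2) / s))
      }
    }
    if (method == "sd") mean(sds) else sqrt(mean(sds^2))
  })
}

# Brute-force epoch enumeration with boundary rejection.
oracle_epoch_starts <- function(n, fs, len_s, overlap, boundaries) {
  len <- len_s * fs
  step <- len_s * (1 - overlap) * fs
  starts <- c()
  s0 <- 1
  while (s0 + len - 1 <= n) {
    covered <- FALSE
    for (b in boundaries) {
      if (b >= s0 && b <= s0 + len - 1) covered <- TRUE
    }
    if (!covered) starts <- c(starts, s0)
    s0 <- s0 + step
  }
  starts
}

# ICC(1,k) from an explicit one-way ANOVA via stats::aov.
oracle_icc1k <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(nrow(m)), ncol(m))))
  tab <- summary(stats::aov(y ~ subj, data = d))[[1]]
  msb <- tab["subj", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / msb
}

# Cronbach's alpha from the covariance matrix:
# alpha = k/(k-1) * (1 - tr(C)/sum(C)).
oracle_alpha <- function(m) {
  C <- stats::cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# Partial Spearman correlation via an explicit projection matrix applied
# to the ranked variables.
oracle_partial_spearman <- function(x, y, Z) {
  rx <- rank(x)
  ry <- rank(y)
  RZ <- apply(as.matrix(Z), 2, rank)
  X <- cbind(1, RZ)
  Pp <- diag(length(x)) - X %*% solve(crossprod(X)) %*% t(X)
  ex <- Pp %*% rx
  ey <- Pp %*% ry
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}
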