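# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Exact optimal 1-D k-clustering by dynamic programming (optimal clusters
# of sorted 1-D data are contiguous). Returns the minimal total
# within-cluster sum of squares. O(k n^2).
dp_kmeans_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse <- function(i, j) {
    # within-SS of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, k, n)
  for (j in 1:n) dp[1, j] <- sse(1, j)
  if (k > 1) {
    for (kk in 2:k) {
      for (j in kk:n) {
        best <- Inf
        for (m in (kk - 1):(j - 1)) {
          cand <- dp[kk - 1, m] + sse(m + 1, j)
          if (cand < best) best <- cand
        }
        dp[kk, j] <- best
      }
    }
  }
  dp[k, n]
}

# Complex frequency response of a digital filter (b, a) at frequency f_hz
# for sampling rate rate_hz, by direct polynomial evaluation.
digital_gain <- function(b, a, f_hz, rate_hz) {
  w <- 2 * pi * f_hz / rate_hz
  z <- exp(-1i * w * (seq_along(b) - 1))
  num <- sum(b * z)
  z <- exp(-1i * w * (seq_along(a) - 1))
  den <- sum(a * z)
  abs(num / den)
}

# Brute-force one-way ANOVA from sums of squares.
anova_by_hand <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, dfb = dfb, dfw = dfw, ssb = ssb, ssw = ssw,
       eta = ssb / (ssb + ssw), p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}

# Amplitude of a sinusoidal component at frequency f in a uniformly
# sampled series, by least squares on sin/cos regressors (mid-series).
fitted_amplitude <- function(x, f_hz, rate_hz) {
  n <- length(x)
  idx <- seq(floor(n / 3), ceiling(2 * n / 3))
  t <- (idx - 1) / rate_hz
  X <- cbind(sin(2 * pi * f_hz * t), cos(2 * pi * f_hz * t))
  cf <- stats::lm.fit(X, x[idx] - mean(x[idx]))$coefficients
  sqrt(sum(cf^2))
}
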