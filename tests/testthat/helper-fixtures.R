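# Shared fixture builders; everything is generated in code at test time.

# Deterministic small series: sinusoid + linear trend per channel, so values
# are distinct and non-degenerate.
toy_series <- function(n = 100, fs = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- sapply(1:6, function(j) sin(seq_len(n) / (3 + j)) + j / 10 +
                if (is.null(seed)) 0 else rnorm(n, 0, 0.05))
  imu_series(matrix(x, ncol = 6), subject_id = "toy", sampling_rate_hz = fs)
}

# Two-regime series with a single multivariate mean shift at `change_at`.
shift_series <- function(n = 6000, change_at = 3000, delta = 1, sd = 0.2,
                         seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 6, 0, sd), n, 6)
  x[(change_at + 1):n, ] <- x[(change_at + 1):n, ] +
    matrix(delta, n - change_at, 6)
  imu_series(x, subject_id = "shift")
}

# Fake labelled feature table with two well-separated Gaussian classes.
fake_feature_table <- function(n = 40, sep = 6, block_size = 800, seed = 1,
                               frac_functional = 0.5) {
  set.seed(seed)
  lab <- rep(c("functional", "nonfunctional"),
             c(round(n * frac_functional), n - round(n * frac_functional)))
  centers <- ifelse(lab == "functional", sep / 2, -sep / 2)
  feats <- sapply(seq_along(wearfu:::FEATURE_NAMES), function(j)
    rnorm(n, centers, 1))
  colnames(feats) <- wearfu:::FEATURE_NAMES
  df <- data.frame(start = (seq_len(n) - 1) * block_size,
                   end = seq_len(n) * block_size,
                   method = "fixed", ground_truth = lab, purity = 1,
                   excluded_frac = 0, block_size = block_size)
  cbind(df, as.data.frame(feats))
}

# Short-duration generator config for unit tests (acceptance tests use the
# 10-minute default).
quick_config <- function(duration_s = 120, ...) {
  generator_config(duration_s = duration_s, ...)
}

# Literal element-by-element two-sample Hotelling T2, written independently
# of the package implementation (loops, explicit pooled covariance).
t2_oracle <- function(a, b) {
  m <- nrow(a); n <- nrow(b); p <- ncol(a)
  ma <- numeric(p); mb <- numeric(p)
  for (j in 1:p) { ma[j] <- sum(a[, j]) / m; mb[j] <- sum(b[, j]) / n }
  sa <- matrix(0, p, p); sb <- matrix(0, p, p)
  for (i in 1:m) sa <- sa + tcrossprod(a[i, ] - ma)
  for (i in 1:n) sb <- sb + tcrossprod(b[i, ] - mb)
  s <- (sa + sb) / (m + n - 2)
  d <- ma - mb
  (m * n / (m + n)) * drop(t(d) %*% solve(s) %*% d)
}
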