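#' Histogram Shannon entropy of a signal block
#'
#' The block is binned into `n_bins` equal-width bins spanning its own
#' `[min, max]` range (so the feature is invariant to affine rescaling of
#' the signal); the entropy is `-sum(p * log2(p))` over non-empty bins, in
#' bits. A constant block has a single occupied bin and entropy 0.
#'
#' @param x numeric vector with at least one sample.
#' @param n_bins number of histogram bins (default 16).
#' @return entropy in bits, in `[0, log2(n_bins)]`.
#' @export
shannon_entropy <- function(x, n_bins = 16L) {
  if (length(x) < 1L) stop("empty signal")
  if (anyNA(x) || any(!is.finite(x))) stop("data error: non-finite values")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  idx <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins)
  idx[idx == n_bins] <- n_bins - 1L  # x == max falls in the last bin
  p <- tabulate(idx + 1L, nbins = n_bins)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Zero-lag cross-correlation of a linear and an angular channel
#'
#' Pearson correlation at lag zero. If either input has zero variance the
#' coefficient is undefined and 0 is returned.
#'
#' @param x,y equal-length numeric vectors (length >= 2).
#' @return correlation in `[-1, 1]`.
#' @export
cross_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("shape error: unequal lengths")
  if (length(x) < 2L) stop("need at least 2 samples")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

#' Block feature vector
#'
#' Computes the 21 features used by the classifier: per-channel histogram
#' entropy, mean and variance (6 channels each) plus the zero-lag
#' cross-correlation of the three axis-matched accelerometer/gyroscope pairs
#' (ax-gx, ay-gy, az-gz). Variance uses the n-1 denominator.
#'
#' @param series an [imu_series()].
#' @param start,end half-open 0-based block interval.
#' @param n_bins entropy histogram bins.
#' @return named numeric vector of the 21 features.
#' @export
extract_features <- function(series, start, end, n_bins = 16L) {
  n <- n_samples(series)
  if (start < 0 || end > n || end <= start)
    stop("domain error: block [", start, ",", end, ") out of bounds")
  w <- series$channels[(start + 1):end, , drop = FALSE]
  ent <- apply(w, 2, shannon_entropy, n_bins = n_bins)
  mu <- colMeans(w)
  v <- apply(w, 2, stats::var)
  xc <- vapply(1:3, function(i) cross_correlation(w[, i], w[, i + 3]),
               numeric(1))
  stats::setNames(c(ent, mu, v, xc), FEATURE_NAMES)
}

#' Feature table for a set of blocks
#'
#' One row per block: `start`, `end`, `block_size` (= end - start, carried
#' for size-weighted accuracy, not used as a classifier input), the block's
#' ground-truth columns if present, and the 21 features.
#'
#' @param series an [imu_series()].
#' @param blocks data frame of blocks, optionally already labelled by
#'   [label_blocks()].
#' @param n_bins entropy histogram bins.
#' @return data frame with metadata columns followed by feature columns.
#' @export
feature_table <- function(series, blocks, n_bins = 16L) {
  feats <- t(vapply(seq_len(nrow(blocks)),
                    function(i) extract_features(series, blocks$start[i],
                                                 blocks$end[i], n_bins),
                    numeric(length(FEATURE_NAMES))))
  meta <- blocks
  meta$block_size <- blocks$end - blocks$start
  cbind(meta, as.data.frame(feats))
}
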