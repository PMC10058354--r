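#' Segmentation parameters
#'
#' Defaults follow the block design used throughout the package: fixed
#' 800-sample blocks (4 s at 200 Hz), and for the variable method a
#' 2000-sample probe window advanced in 600-sample shifts, with the change
#' threshold calibrated to an 80% true-positive rate on labelled transitions.
#'
#' @param fixed_block fixed block length in samples (default 800).
#' @param probe_block probe window length for the change detector (2000).
#' @param shift candidate-boundary step in samples (600).
#' @param t2_threshold Hotelling T-squared change threshold; `NULL` until
#'   calibrated with [calibrate_threshold()].
#' @param target_tpr calibration target true-positive rate (default 0.80).
#' @param ridge_eps relative ridge added to the pooled covariance before
#'   inversion (scaled by the mean of its diagonal; guards near-singular
#'   covariance on low-variance rest data).
#' @return a list of class `segmentation_config`.
#' @export
segmentation_config <- function(fixed_block = 800L, probe_block = 2000L,
                                shift = 600L, t2_threshold = NULL,
                                target_tpr = 0.80, ridge_eps = 1e-6) {
  stopifnot(fixed_block >= 2, probe_block >= 2, shift >= 1,
            shift <= probe_block, target_tpr >= 0, target_tpr < 1,
            ridge_eps >= 0)
  structure(list(fixed_block = as.integer(fixed_block),
                 probe_block = as.integer(probe_block),
                 shift = as.integer(shift),
                 t2_threshold = t2_threshold,
                 target_tpr = target_tpr, ridge_eps = ridge_eps),
            class = "segmentation_config")
}

#' Fixed-length segmentation
#'
#' Cuts the series into consecutive non-overlapping blocks of
#' `fixed_block` samples starting at 0; a trailing remainder shorter than
#' one block is discarded.
#'
#' @param series an [imu_series()].
#' @param fixed_block block length in samples (default 800, i.e. 4 s at
#'   200 Hz).
#' @return data frame with 0-based half-open `start`/`end` columns and a
#'   `method` column equal to `"fixed"`.
#' @export
segment_fixed <- function(series, fixed_block = 800L) {
  n <- n_samples(series)
  k <- n %/% fixed_block
  if (k == 0L) {
    warning("series shorter than one fixed block; no blocks produced")
    return(data.frame(start = integer(0), end = integer(0),
                      method = character(0)))
  }
  data.frame(start = (seq_len(k) - 1L) * as.integer(fixed_block),
             end = seq_len(k) * as.integer(fixed_block),
             method = "fixed")
}

#' Two-sample Hotelling T-squared statistic
#'
#' For windows A (m x p) and B (n x p),
#' `T2 = (m n / (m + n)) * d' S^-1 d`, with `d` the difference of column
#' means and `S` the pooled sample covariance, ridged by
#' `ridge_eps * mean(diag(S)) * I` before inversion. Large values indicate
#' that the two windows have different multivariate means.
#'
#' @param a,b numeric matrices with the same number of columns and at least
#'   2 rows each.
#' @param ridge_eps relative ridge regularizer (see [segmentation_config()]).
#' @return the non-negative statistic.
#' @export
hotelling_t2 <- function(a, b, ridge_eps = 1e-6) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("domain error: both windows need at least 2 rows")
  if (ncol(a) != ncol(b)) stop("windows must have the same number of columns")
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b)))
    stop("data error: non-finite values in window")
  m <- nrow(a); n <- nrow(b); p <- ncol(a)
  d <- colMeans(a) - colMeans(b)
  s <- ((m - 1) * stats::cov(a) + (n - 1) * stats::cov(b)) / (m + n - 2)
  .t2_from_stats(d, s, m, n, ridge_eps)
}

.t2_from_stats <- function(d, s, m, n, ridge_eps) {
  scale <- mean(diag(s))
  if (scale <= 0) return(0)  # both windows constant: no mean difference metric
  s_reg <- s + diag(ridge_eps * scale, nrow(s))
  drop((m * n / (m + n)) * crossprod(d, solve(s_reg, d)))
}

# Cumulative first/second-moment sums over the 6 channels so that the mean
# and covariance of any window are O(1) to obtain; used by the sequential
# detector and the threshold sweep, where the same boundary statistic is
# evaluated many times.
.series_cumstats <- function(series) {
  x <- series$channels
  p <- ncol(x)
  cs1 <- apply(x, 2, cumsum)
  cross <- matrix(0, nrow(x), p * (p + 1) / 2)
  k <- 0
  for (i in seq_len(p)) for (j in i:p) {
    k <- k + 1
    cross[, k] <- cumsum(x[, i] * x[, j])
  }
  list(n = nrow(x), p = p, cs1 = rbind(0, cs1), cs2 = rbind(0, cross))
}

.window_moments <- function(cs, start, end) {
  n <- end - start
  s1 <- cs$cs1[end + 1, ] - cs$cs1[start + 1, ]
  s2v <- cs$cs2[end + 1, ] - cs$cs2[start + 1, ]
  p <- cs$p
  s2 <- matrix(0, p, p)
  k <- 0
  for (i in seq_len(p)) for (j in i:p) {
    k <- k + 1
    s2[i, j] <- s2[j, i] <- s2v[k]
  }
  mu <- s1 / n
  covm <- (s2 - n * tcrossprod(mu)) / (n - 1)
  list(mu = mu, cov = covm, n = n)
}

# T2 between the trailing probe window [b - probe, b) and the leading probe
# window [b, b + probe): a pure function of the candidate boundary b.
.t2_at_boundary <- function(cs, b, probe, ridge_eps) {
  wa <- .window_moments(cs, b - probe, b)
  wb <- .window_moments(cs, b, b + probe)
  s <- ((wa$n - 1) * wa$cov + (wb$n - 1) * wb$cov) / (wa$n + wb$n - 2)
  .t2_from_stats(wa$mu - wb$mu, s, wa$n, wb$n, ridge_eps)
}

#' Variable-length segmentation by a block-growing change detector
#'
#' Grows the current segment from its start `s`: the first candidate
#' boundary is `b = s + probe_block`; the trailing `probe_block` samples of
#' the segment are compared against the next `probe_block` samples with
#' [hotelling_t2()]. If the statistic exceeds the threshold, the segment is
#' closed at `b` and a new one starts there; otherwise `b` advances by
#' `shift` and the test repeats. When fewer than `probe_block` samples
#' remain beyond `b`, the final segment is closed at the end of the series,
#' so the returned blocks always partition `[0, n_samples)`. Segment
#' lengths are therefore `probe_block + shift * k` except for a possible
#' shorter terminal block.
#'
#' @param series an [imu_series()].
#' @param config a [segmentation_config()] whose `t2_threshold` is set.
#' @return data frame of blocks (`start`, `end`, `method = "variable"`)
#'   with the tested candidate boundaries and their statistics attached as
#'   attribute `"trace"` (columns `b`, `t2`, `declared`).
#' @export
segment_variable <- function(series, config) {
  stopifnot(inherits(config, "segmentation_config"))
  if (is.null(config$t2_threshold))
    stop("config$t2_threshold is not set; run calibrate_threshold() first")
  n <- n_samples(series)
  probe <- config$probe_block
  if (n < 2L * probe) {
    warning("series shorter than two probe windows; returning a single block")
    blocks <- data.frame(start = 0L, end = n, method = "variable")
    attr(blocks, "trace") <- data.frame(b = integer(0), t2 = numeric(0),
                                        declared = logical(0))
    return(blocks)
  }
  cs <- .series_cumstats(series)
  starts <- integer(0); ends <- integer(0)
  trace_b <- integer(0); trace_t2 <- numeric(0); trace_dec <- logical(0)
  s <- 0L
  b <- probe
  repeat {
    if (b + probe > n) {
      starts <- c(starts, s); ends <- c(ends, n)
      break
    }
    t2 <- .t2_at_boundary(cs, b, probe, config$ridge_eps)
    declared <- t2 > config$t2_threshold
    trace_b <- c(trace_b, b); trace_t2 <- c(trace_t2, t2)
    trace_dec <- c(trace_dec, declared)
    if (declared) {
      starts <- c(starts, s); ends <- c(ends, b)
      s <- b
      b <- s + probe
    } else {
      b <- b + config$shift
    }
  }
  blocks <- data.frame(start = starts, end = ends, method = "variable")
  attr(blocks, "trace") <- data.frame(b = trace_b, t2 = trace_t2,
                                      declared = trace_dec)
  blocks
}

#' Fraction of true transitions matched by declared boundaries
#'
#' A transition counts as detected when some declared boundary lies within
#' `tol` samples of it.
#'
#' @param boundaries integer vector of declared internal boundaries
#'   (segment end points, excluding the end of the series).
#' @param transitions integer vector of true transition sample indices.
#' @param tol matching tolerance in samples (default 600, one shift).
#' @return the true-positive rate in `[0, 1]`.
#' @export
transition_tpr <- function(boundaries, transitions, tol = 600) {
  if (length(transitions) == 0L) stop("no transitions to score")
  if (length(boundaries) == 0L) return(0)
  hit <- vapply(transitions,
                function(tr) any(abs(boundaries - tr) <= tol), logical(1))
  mean(hit)
}

.internal_boundaries <- function(blocks) {
  ends <- blocks$end
  if (length(ends) <= 1L) integer(0) else ends[-length(ends)]
}

#' Calibrate the change threshold to a target true-positive rate
#'
#' Sweeps candidate thresholds over the boundary statistics observed on the
#' training series (the sequential detector is re-run per candidate; the
#' statistic at each boundary is cached, as it depends only on the boundary
#' position). A true transition counts as detected when a declared boundary
#' falls within `config$shift` samples of it. The largest threshold whose
#' pooled true-positive rate reaches `config$target_tpr` is returned, i.e.
#' the most conservative detector that still finds the target share of
#' transitions. If no threshold reaches the target, the threshold with
#' maximal TPR is returned with a warning.
#'
#' @param series_list list of [imu_series()] training recordings.
#' @param transitions_list list of integer vectors of true transition
#'   samples, parallel to `series_list`.
#' @param config a [segmentation_config()].
#' @param n_candidates maximum number of candidate thresholds examined
#'   (quantile-thinned from the observed statistics).
#' @return the input `config` with `t2_threshold` set; the achieved TPR is
#'   attached as attribute `"tpr"`.
#' @export
calibrate_threshold <- function(series_list, transitions_list, config,
                                n_candidates = 80L) {
  stopifnot(length(series_list) == length(transitions_list),
            length(series_list) >= 1L)
  if (sum(lengths(transitions_list)) < 5L)
    stop("need at least 5 true transitions across the training series")
  caches <- lapply(series_list, .series_cumstats)
  t2_memo <- lapply(series_list, function(s) new.env(parent = emptyenv()))
  t2_of <- function(i, b) {
    key <- as.character(b)
    env <- t2_memo[[i]]
    if (is.null(env[[key]]))
      env[[key]] <- .t2_at_boundary(caches[[i]], b, config$probe_block,
                                    config$ridge_eps)
    env[[key]]
  }
  run_one <- function(i, threshold) {
    n <- caches[[i]]$n
    probe <- config$probe_block
    ends <- integer(0)
    s <- 0L; b <- probe
    while (b + probe <= n) {
      if (t2_of(i, b) > threshold) {
        ends <- c(ends, b); s <- b; b <- s + probe
      } else b <- b + config$shift
    }
    ends
  }
  tpr_at <- function(threshold) {
    hits <- 0L; total <- 0L
    for (i in seq_along(series_list)) {
      ends <- run_one(i, threshold)
      tr <- transitions_list[[i]]
      total <- total + length(tr)
      if (length(ends))
        hits <- hits + sum(vapply(tr, function(t0)
          any(abs(ends - t0) <= config$shift), logical(1)))
    }
    hits / total
  }
  # observed statistics on the base candidate lattice (threshold = Inf path)
  observed <- unlist(lapply(seq_along(series_list), function(i) {
    n <- caches[[i]]$n
    bs <- seq(config$probe_block, n - config$probe_block, by = config$shift)
    vapply(bs, function(b) t2_of(i, b), numeric(1))
  }))
  cand <- sort(unique(stats::quantile(observed,
                                      probs = seq(0, 1, length.out = n_candidates),
                                      names = FALSE, type = 1)),
               decreasing = TRUE)
  best_thr <- NA_real_; best_tpr <- -1
  for (thr in cand) {
    tpr <- tpr_at(thr)
    if (tpr > best_tpr) { best_tpr <- tpr; best_thr <- thr }
    if (tpr >= config$target_tpr) {
      config$t2_threshold <- thr
      attr(config, "tpr") <- tpr
      return(config)
    }
  }
  warning(sprintf("no threshold reaches target TPR %.2f; best achieved %.2f",
                  config$target_tpr, best_tpr))
  config$t2_threshold <- best_thr
  attr(config, "tpr") <- best_tpr
  config
}
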