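#' Chunk-size-weighted accuracy
#'
#' The sample counts of correctly classified blocks are summed and divided
#' by the total sample count, so a long block counts proportionally more
#' than a short one. With equal block sizes this reduces to plain accuracy.
#'
#' @param correct logical vector, one flag per block.
#' @param sizes positive block sizes in samples, same length.
#' @return accuracy in `[0, 1]`.
#' @export
weighted_accuracy <- function(correct, sizes) {
  if (length(correct) == 0L) stop("domain error: no blocks")
  if (length(correct) != length(sizes)) stop("shape error: unequal lengths")
  if (any(sizes <= 0)) stop("domain error: block sizes must be positive")
  sum(sizes[correct]) / sum(sizes)
}

#' Percent of time in functional use
#'
#' Size-weighted share of blocks labelled functional, as a percentage of all
#' non-excluded block time (equivalently, percent of time, since block size
#' is proportional to duration).
#'
#' @param labels block labels (`"functional"`, `"nonfunctional"`,
#'   `"excluded"`).
#' @param sizes block sizes in samples.
#' @return percentage in `[0, 100]`.
#' @export
functional_use_percent <- function(labels, sizes) {
  keep <- labels %in% c("functional", "nonfunctional")
  if (!any(keep)) stop("domain error: all blocks excluded")
  100 * sum(sizes[keep & labels == "functional"]) / sum(sizes[keep])
}

#' Absolute error of a functional-use estimate
#' @param predicted,truth percentages in `[0, 100]`.
#' @return `|predicted - truth|` in percentage points.
#' @export
fu_error <- function(predicted, truth) {
  stopifnot(all(predicted >= 0 & predicted <= 100),
            all(truth >= 0 & truth <= 100))
  abs(predicted - truth)
}

#' Median and range summary
#'
#' Nonparametric summary used throughout reporting: the sample median (mean
#' of the two central order statistics for even n) with the minimum and
#' maximum.
#'
#' @param values numeric vector with at least one value.
#' @return named numeric vector `c(median, min, max)`.
#' @export
median_range <- function(values) {
  if (length(values) == 0L || anyNA(values)) stop("domain error: empty input")
  c(median = stats::median(values), min = min(values), max = max(values))
}

#' Mann-Whitney U test between two independent groups
#'
#' Returns the U statistic of the first group and a two-sided p-value:
#' exact (from the null U distribution) when there are no ties and
#' `nA + nB <= 20`, otherwise the normal approximation with tie correction
#' and no continuity correction.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p-value;
#'   default `NULL` picks automatically as above.
#' @return list with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop("domain error: empty group")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (is.null(exact)) exact <- !has_ties && (na + nb) <= 20
  if (exact && has_ties)
    stop("exact p-value unavailable with ties")
  if (exact) {
    u_low <- min(u, na * nb - u)
    p <- min(1, 2 * stats::pwilcox(u_low, na, nb))
    method <- "exact"
  } else {
    n <- na + nb
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    z <- (u - na * nb / 2) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(U = u, p = p, method = method)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped. The statistic is the sum of the ranks of
#' the positive differences. The p-value is exact (from the null signed-rank
#' distribution) when there are no ties among the absolute differences and
#' at most 25 remain; otherwise a tie-corrected normal approximation without
#' continuity correction is used. Set `exact = FALSE` to force the
#' approximation (the convention some statistics packages apply at any n).
#'
#' @param x numeric vector: paired differences, or first member of pairs if
#'   `y` is given.
#' @param y optional second member of the pairs.
#' @param exact force or forbid the exact p-value (default `NULL`: auto).
#' @return list with `V` (positive-rank sum), `p`, `n` (non-zero pairs) and
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate-input error: all differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (is.null(exact)) exact <- !has_ties && n <= 25
  if (exact && has_ties) stop("exact p-value unavailable with ties")
  if (exact) {
    p <- min(1, 2 * min(stats::psignrank(v, n),
                        1 - stats::psignrank(v - 1, n)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(V = v, p = p, n = n, method = method)
}

#' Aggregate per-subject results into a cohort report
#'
#' Takes a per-subject table of metrics (one row per subject; numeric
#' metric columns plus optional `subject`/`group` identifiers) and computes
#' the median-and-range summary of every metric. When two groups are
#' present, each metric is additionally compared between groups with the
#' Mann-Whitney U test.
#'
#' @param per_subject data frame, one row per subject.
#' @param paired_tests optional named list of column pairs, e.g.
#'   `list(intra = c("acc_intra_fixed", "acc_intra_variable"))`; each pair
#'   is compared with the Wilcoxon signed-rank test across subjects.
#' @return list of class `evaluation_report` with `per_subject`, `summary`
#'   (per group), `group_tests` and `paired_tests`.
#' @export
build_report <- function(per_subject, paired_tests = NULL) {
  if (!is.data.frame(per_subject) || nrow(per_subject) == 0L)
    stop("per_subject must be a non-empty data frame")
  metric_cols <- names(per_subject)[vapply(per_subject, is.numeric, logical(1))]
  groups <- if ("group" %in% names(per_subject)) unique(per_subject$group)
            else "all"
  summarise_rows <- function(rows) {
    out <- lapply(metric_cols, function(mc) median_range(rows[[mc]]))
    names(out) <- metric_cols
    out
  }
  summary <- lapply(groups, function(g) {
    rows <- if ("group" %in% names(per_subject))
      per_subject[per_subject$group == g, , drop = FALSE] else per_subject
    summarise_rows(rows)
  })
  names(summary) <- groups
  group_tests <- NULL
  if (length(groups) == 2L) {
    g1 <- per_subject[per_subject$group == groups[1], , drop = FALSE]
    g2 <- per_subject[per_subject$group == groups[2], , drop = FALSE]
    group_tests <- lapply(metric_cols, function(mc)
      tryCatch(mann_whitney_u(g1[[mc]], g2[[mc]]), error = function(e) NULL))
    names(group_tests) <- metric_cols
  }
  paired <- NULL
  if (!is.null(paired_tests)) {
    paired <- lapply(paired_tests, function(pair)
      tryCatch(wilcoxon_signed_rank(per_subject[[pair[1]]],
                                    per_subject[[pair[2]]]),
               error = function(e) NULL))
  }
  structure(list(per_subject = per_subject, summary = summary,
                 group_tests = group_tests, paired_tests = paired),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  cat("<evaluation_report>\n")
  for (g in names(x$summary)) {
    cat(sprintf("  group %s (n = %d):\n", g,
                if ("group" %in% names(x$per_subject))
                  sum(x$per_subject$group == g) else nrow(x$per_subject)))
    for (mc in names(x$summary[[g]])) {
      s <- x$summary[[g]][[mc]]
      cat(sprintf("    %-24s %s (%s-%s)\n", mc,
                  format(round(s["median"], digits)),
                  format(round(s["min"], digits)),
                  format(round(s["max"], digits))))
    }
  }
  invisible(x)
}

#' Render an evaluation report as markdown tables
#' @param report an [build_report()] result.
#' @param digits decimals for percentages (default 2).
#' @return character vector of markdown lines.
#' @export
render_report_md <- function(report, digits = 2) {
  ps <- report$per_subject
  metric_cols <- names(ps)[vapply(ps, is.numeric, logical(1))]
  lines <- c("| subject | " %+% paste(metric_cols, collapse = " | ") %+% " |",
             "|" %+% paste(rep("---|", length(metric_cols) + 1), collapse = ""))
  for (i in seq_len(nrow(ps))) {
    vals <- vapply(metric_cols, function(mc) format(round(ps[[mc]][i], digits)),
                   character(1))
    id <- if ("subject" %in% names(ps)) as.character(ps$subject[i]) else i
    lines <- c(lines, "| " %+% id %+% " | " %+%
                 paste(vals, collapse = " | ") %+% " |")
  }
  for (g in names(report$summary)) {
    s <- report$summary[[g]]
    vals <- vapply(metric_cols, function(mc)
      sprintf("%s (%s-%s)", format(round(s[[mc]]["median"], digits)),
              format(round(s[[mc]]["min"], digits)),
              format(round(s[[mc]]["max"], digits))), character(1))
    lines <- c(lines, "| median (range), " %+% g %+% " | " %+%
                 paste(vals, collapse = " | ") %+% " |")
  }
  lines
}

`%+%` <- function(a, b) paste0(a, b)
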