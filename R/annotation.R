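#' Fuse per-sample codes from multiple annotators by majority vote
#'
#' Per sample, the code on which at least two of three annotators agree is
#' kept. If no majority exists, or the majority code is -1 (unknown), the
#' sample is coded -1 and is excluded downstream. With two annotators, full
#' agreement is required; a single track is returned unchanged.
#'
#' @param codes integer matrix of per-sample codes, one column per annotator
#'   (1-3 columns), e.g. the output of [align_annotations()].
#' @return integer vector of merged FAABOS codes, one per sample.
#' @export
merge_annotators <- function(codes) {
  if (is.vector(codes)) codes <- matrix(as.integer(codes), ncol = 1)
  if (!all(codes %in% FAABOS_CODES))
    stop("domain error: codes must lie in {-1, 0, 1, 2, 3}")
  k <- ncol(codes)
  merged <- switch(as.character(k),
    "1" = codes[, 1],
    "2" = ifelse(codes[, 1] == codes[, 2], codes[, 1], -1L),
    "3" = {
      a <- codes[, 1]; b <- codes[, 2]; c <- codes[, 3]
      out <- ifelse(a == b | a == c, a, ifelse(b == c, b, -1L))
      out
    },
    stop("shape error: 1-3 annotator columns required"))
  as.integer(merged)
}

#' Collapse FAABOS codes to the binary functional scheme
#'
#' Codes 2 (nontask-related functional) and 3 (task-related) map to
#' `"functional"`; codes 0 (no activity) and 1 (nonfunctional movement) map
#' to `"nonfunctional"`; -1 (unknown) maps to `"excluded"`.
#'
#' @param codes integer vector of merged FAABOS codes.
#' @return character vector in `{"functional","nonfunctional","excluded"}`.
#' @export
collapse_binary <- function(codes) {
  codes <- as.integer(codes)
  if (!all(codes %in% FAABOS_CODES))
    stop("domain error: codes must lie in {-1, 0, 1, 2, 3}")
  out <- rep("excluded", length(codes))
  out[codes %in% c(0L, 1L)] <- "nonfunctional"
  out[codes %in% c(2L, 3L)] <- "functional"
  out
}

#' Majority ground-truth label of one sample block
#'
#' Excluded (unknown) samples are removed from the denominator. The block is
#' `"functional"` if functional samples exceed 50% of the non-excluded
#' samples and `"nonfunctional"` if those exceed 50%; an exact 50/50 tie is
#' assigned to `"nonfunctional"` (the conservative non-use class, since
#' neither class strictly exceeds half). A block in which half or more of
#' the samples are excluded is itself `"excluded"`.
#'
#' @param start,end half-open 0-based sample interval `[start, end)`.
#' @param binary per-sample labels from [collapse_binary()], full series.
#' @return list with `label`, `purity` (largest class share among
#'   non-excluded samples; `NA` for excluded blocks) and `excluded_frac`.
#' @export
block_label <- function(start, end, binary) {
  if (end <= start || start < 0 || end > length(binary))
    stop("domain error: block [", start, ",", end, ") out of bounds")
  lab <- binary[(start + 1):end]
  n <- length(lab)
  n_f <- sum(lab == "functional")
  n_nf <- sum(lab == "nonfunctional")
  n_known <- n_f + n_nf
  excluded_frac <- 1 - n_known / n
  if (n_known <= n / 2)
    return(list(label = "excluded", purity = NA_real_,
                excluded_frac = excluded_frac))
  purity <- max(n_f, n_nf) / n_known
  label <- if (n_f > n_known / 2) "functional" else "nonfunctional"
  list(label = label, purity = purity, excluded_frac = excluded_frac)
}

#' Label a table of blocks with majority ground truth
#'
#' @param blocks data frame with `start`/`end` columns (e.g. from
#'   [segment_fixed()] or [segment_variable()]).
#' @param binary per-sample binary labels for the whole series.
#' @return `blocks` with `ground_truth`, `purity` and `excluded_frac`
#'   columns appended.
#' @export
label_blocks <- function(blocks, binary) {
  res <- lapply(seq_len(nrow(blocks)),
                function(i) block_label(blocks$start[i], blocks$end[i], binary))
  blocks$ground_truth <- vapply(res, `[[`, character(1), "label")
  blocks$purity <- vapply(res, `[[`, numeric(1), "purity")
  blocks$excluded_frac <- vapply(res, `[[`, numeric(1), "excluded_frac")
  blocks
}

#' Export merged per-sample labels as TSV
#'
#' Writes columns `sample` (0-based), `faabos` (merged code) and `binary`.
#'
#' @param merged integer vector of merged FAABOS codes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(merged, path) {
  df <- data.frame(sample = seq_along(merged) - 1L, faabos = merged,
                   binary = collapse_binary(merged))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
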