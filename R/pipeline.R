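#' Segment, label and featurize one subject
#'
#' Runs one segmentation method over a subject dataset, assigns majority
#' ground truth per block from the merged annotation labels, and computes
#' the 21-feature table.
#'
#' @param dataset a [subject_dataset()] (or any list with `series` and
#'   `binary` fields).
#' @param method `"fixed"` or `"variable"`.
#' @param seg_config a [segmentation_config()]; for the variable method its
#'   `t2_threshold` must be set.
#' @return labelled feature table (one row per block).
#' @export
prepare_blocks <- function(dataset, method = c("fixed", "variable"),
                           seg_config = segmentation_config()) {
  method <- match.arg(method)
  blocks <- if (method == "fixed")
    segment_fixed(dataset$series, seg_config$fixed_block)
  else segment_variable(dataset$series, seg_config)
  blocks <- label_blocks(blocks, dataset$binary)
  feature_table(dataset$series, blocks)
}

#' Evaluate a cohort with both protocols
#'
#' End-to-end driver: featurizes every subject with the requested
#' segmentation method, then runs intra-subject 10-fold cross-validation and
#' inter-subject leave-one-subject-out, and derives per-subject
#' functional-use estimates. Ground-truth FU% is computed from the merged
#' per-sample annotation labels; predicted FU% from the predicted block
#' labels of each protocol (size-weighted).
#'
#' @param datasets named list of [subject_dataset()] objects, one group.
#' @param method `"fixed"` or `"variable"`.
#' @param seg_config a [segmentation_config()] (threshold set when
#'   `method = "variable"`).
#' @param forest a [forest_config()].
#' @param k intra-subject folds.
#' @param protocol_seed seed for fold partitions.
#' @return list with `per_subject` (data frame: accuracies, FU estimates,
#'   errors), `intra` and `inter` (lists of `protocol_result`).
#' @export
evaluate_cohort <- function(datasets, method = c("fixed", "variable"),
                            seg_config = segmentation_config(),
                            forest = forest_config(), k = 10L,
                            protocol_seed = 1L) {
  method <- match.arg(method)
  groups <- vapply(datasets, `[[`, character(1), "group")
  if (length(unique(groups)) > 1L)
    stop("protocol error: cohort mixes groups; evaluate groups separately")
  tables <- lapply(datasets, prepare_blocks, method = method,
                   seg_config = seg_config)
  intra <- lapply(tables, run_intra_subject, method = method, k = k,
                  config = forest, protocol_seed = protocol_seed)
  inter <- run_inter_subject(tables, method = method, config = forest,
                             groups = groups)
  fu_pred <- function(pr) functional_use_percent(pr$predictions$predicted,
                                                 pr$predictions$block_size)
  truth_fu <- vapply(datasets, function(d)
    functional_use_percent(collapse_binary(d$merged_codes),
                           rep(1, length(d$merged_codes))), numeric(1))
  per_subject <- data.frame(
    subject = names(datasets),
    group = groups,
    acc_intra = vapply(intra, `[[`, numeric(1), "accuracy"),
    acc_inter = vapply(inter, `[[`, numeric(1), "accuracy"),
    fu_truth = truth_fu,
    fu_intra = vapply(intra, fu_pred, numeric(1)),
    fu_inter = vapply(inter, fu_pred, numeric(1)),
    row.names = NULL)
  per_subject$fu_err_intra <- fu_error(per_subject$fu_intra, per_subject$fu_truth)
  per_subject$fu_err_inter <- fu_error(per_subject$fu_inter, per_subject$fu_truth)
  list(per_subject = per_subject, intra = intra, inter = inter,
       method = method)
}
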