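#' Reference cohort: per-subject benchmark values
#'
#' Bundled per-subject results from a benchmark cohort of 10 control
#' participants (subjects 1-10, non-dominant arm) and 5 prosthesis users
#' (subjects 11-15, prosthetic limb) who performed instrumental activities
#' of daily living (laundry, kitchen cleaning, grocery shopping, bed making)
#' plus non-purposeful movement while wearing the wrist sensor. These tables
#' are the inputs to the package's summary statistics: median/range
#' summaries and the nonparametric group tests are recomputed from them,
#' they are not stored.
#'
#' @return list of three data frames:
#' \describe{
#'   \item{activity}{per-subject minutes in each activity, non-functional
#'     minutes, annotation-derived functional-use percentage, and group.}
#'   \item{accuracy}{prosthesis users' classifier accuracy (percent) for
#'     fixed and variable segmentation under both protocols.}
#'   \item{fu_estimates}{prosthesis users' predicted functional-use
#'     percentage per method/protocol next to annotation ground truth.}
#' }
#' @export
reference_cohort <- function() {
  activity <- data.frame(
    subject = 1:15,
    group = rep(c("control", "amputee"), c(10, 5)),
    laundry    = c(5, 5, 5, 6, 7, 11, 8, 5, 6, 6,   8, 7, 14, 6, 11),
    kitchen    = c(7, 6, 6, 5, 6, 5, 5, 5, 4, 5,    7, 6, 6, 6, 8),
    shopping   = c(5, 7, 5, 4, 4, 6, 3, 3, 2, 4,    4, 4, 5, 4, 5),
    making_bed = c(3, 4, 4, 3, 2, 3, 4, 4, 4, 4,    7, 5, 4, 4, 10),
    nonfunctional_min = c(13, 11, 9, 10, 10, 12, 19, 14, 13, 15,
                          11, 8, 16, 11, 13),
    fu_percent = c(61.46, 55.53, 69.84, 67.92, 63.59, 70.98, 57.30, 67.49,
                   57.11, 58.45,
                   61.23, 70.78, 63.50, 58.33, 74.94))
  activity$activity_min <- with(activity, laundry + kitchen + shopping +
                                  making_bed)
  accuracy <- data.frame(
    subject = 11:15,
    intra_fixed    = c(85.84, 83.73, 82.70, 82.17, 79.31),
    intra_variable = c(50.06, 67.57, 79.88, 69.90, 90.84),
    inter_fixed    = c(61.36, 72.75, 69.75, 63.65, 71.13),
    inter_variable = c(54.22, 66.90, 79.17, 71.60, 80.21))
  fu_estimates <- data.frame(
    subject = 11:15,
    ground_truth   = c(61.23, 70.78, 63.50, 58.33, 74.94),
    intra_fixed    = c(78.98, 60.76, 57.11, 52.45, 73.08),
    intra_variable = c(86.96, 65.66, 51.02, 60.23, 71.67),
    inter_fixed    = c(58.37, 75.11, 64.79, 54.52, 78.82),
    inter_variable = c(60.87, 72.15, 66.67, 64.77, 72.41))
  list(activity = activity, accuracy = accuracy, fu_estimates = fu_estimates)
}

#' Summary statistics of the reference cohort
#'
#' Recomputes, with the package's own operations, every headline summary of
#' the reference cohort: median (range) of classifier accuracies per
#' method/protocol, of functional-use percentages and total activity
#' minutes per group, of the absolute functional-use estimation errors, and
#' the Mann-Whitney group comparisons plus the Wilcoxon fixed-vs-variable
#' method comparisons.
#'
#' @return nested list of `median_range` vectors and test results.
#' @export
reference_summary <- function() {
  ref <- reference_cohort()
  act <- ref$activity
  acc <- ref$accuracy
  fue <- ref$fu_estimates
  ctrl <- act[act$group == "control", ]
  amp <- act[act$group == "amputee", ]
  err <- lapply(fue[c("intra_fixed", "intra_variable",
                      "inter_fixed", "inter_variable")],
                function(col) fu_error(col, fue$ground_truth))
  list(
    accuracy = lapply(acc[-1], median_range),
    fu_percent = list(control = median_range(ctrl$fu_percent),
                      amputee = median_range(amp$fu_percent)),
    activity_min = list(control = median_range(ctrl$activity_min),
                        amputee = median_range(amp$activity_min)),
    fu_error = lapply(err, median_range),
    group_tests = list(
      activity_min = mann_whitney_u(ctrl$activity_min, amp$activity_min),
      fu_percent = mann_whitney_u(ctrl$fu_percent, amp$fu_percent)),
    method_tests = list(
      intra = wilcoxon_signed_rank(acc$intra_fixed, acc$intra_variable,
                                   exact = FALSE),
      inter = wilcoxon_signed_rank(acc$inter_fixed, acc$inter_variable,
                                   exact = FALSE)))
}
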