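#' Random Forest configuration
#'
#' Defaults mirror the forest used throughout the package: 100 trees, seed
#' 123 for repeatability, unlimited depth, no backfitting, and 4 features
#' examined at each split (about the square root of the 21-feature space).
#'
#' @param n_trees number of trees (default 100).
#' @param seed RNG seed set immediately before fitting (default 123).
#' @param features_per_split variables tried at each split (default 4).
#' @return a list of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100L, seed = 123L,
                          features_per_split = 4L) {
  stopifnot(n_trees >= 1, features_per_split >= 1)
  structure(list(n_trees = as.integer(n_trees), seed = as.integer(seed),
                 features_per_split = as.integer(features_per_split)),
            class = "forest_config")
}

.feature_matrix <- function(features) {
  cols <- intersect(FEATURE_NAMES, colnames(features))
  if (length(cols) != length(FEATURE_NAMES))
    stop("feature table is missing feature columns")
  as.matrix(features[, FEATURE_NAMES, drop = FALSE])
}

#' Train the block classifier
#'
#' Fits a seeded Random Forest on the 21 block features. Refitting with the
#' same data and configuration reproduces identical predictions.
#'
#' @param features data frame containing the 21 feature columns (e.g. from
#'   [feature_table()]); metadata columns are ignored.
#' @param labels vector of block labels, exactly the two classes
#'   `"functional"` / `"nonfunctional"` (excluded blocks must be removed
#'   upstream).
#' @param config a [forest_config()].
#' @return fitted model of class `randomForest`.
#' @export
train_forest <- function(features, labels, config = forest_config()) {
  x <- .feature_matrix(features)
  y <- factor(as.character(labels), levels = c("functional", "nonfunctional"))
  if (anyNA(y)) stop("labels must be 'functional' or 'nonfunctional'")
  if (nlevels(droplevels(y)) < 2L || min(table(y)) < 2L)
    stop("degenerate-training error: need at least 2 blocks per class")
  set.seed(config$seed)
  randomForest::randomForest(x = x, y = y, ntree = config$n_trees,
                             mtry = config$features_per_split)
}

#' Predict block classes
#' @param model a fitted forest from [train_forest()].
#' @param features feature table of blocks to classify.
#' @return character vector of predicted labels.
#' @export
predict_forest <- function(model, features) {
  as.character(stats::predict(model, .feature_matrix(features)))
}

# Drop blocks unusable for a given method: annotation-excluded blocks
# always; for the fixed method also "mixed" blocks whose ground-truth
# purity is below the cutoff. The default 0.95 treats a block as mixed only
# when it is structurally mixed (contains a class transition); occasional
# isolated annotation errors (a consensus flip of a frame or two) leave
# purity just below 1 and should not discard an otherwise homogeneous
# block. Set the cutoff to 1.0 for the strict any-two-classes rule.
.usable_blocks <- function(features, method, purity_cutoff = 0.95) {
  keep <- features$ground_truth %in% c("functional", "nonfunctional")
  if (method == "fixed") keep <- keep & features$purity >= purity_cutoff
  features[keep, , drop = FALSE]
}

#' Intra-subject 10-fold cross-validation
#'
#' Blocks of one subject are partitioned uniformly at random into `k` folds
#' (seeded, unstratified); each fold is predicted by a forest trained on the
#' other folds, so every block is tested exactly once. Accuracy is
#' chunk-size weighted, which reduces to plain accuracy for fixed blocks.
#' For the fixed method, mixed blocks (ground-truth purity below
#' `purity_cutoff`) are excluded from both training and testing; the
#' variable method uses all majority-labelled blocks.
#'
#' @param features labelled feature table of one subject ([feature_table()]
#'   on blocks processed by [label_blocks()]).
#' @param method `"fixed"` or `"variable"`.
#' @param k number of folds (default 10).
#' @param config a [forest_config()].
#' @param protocol_seed seed for the fold partition.
#' @param purity_cutoff fixed-method mixed-block cutoff (default 0.95:
#'   blocks containing a genuine class transition are dropped, while
#'   near-pure blocks carrying an isolated annotation error are kept;
#'   1.0 gives the strict rule that any block containing both classes is
#'   mixed).
#' @return list of class `protocol_result` with fields `protocol`,
#'   `method`, `accuracy` and `predictions` (the usable feature table plus
#'   `predicted` and `correct` columns; functional-use estimates are
#'   derived from the same block set).
#' @export
run_intra_subject <- function(features, method = c("fixed", "variable"),
                              k = 10L, config = forest_config(),
                              protocol_seed = 1L, purity_cutoff = 0.95) {
  method <- match.arg(method)
  usable <- .usable_blocks(features, method, purity_cutoff)
  n <- nrow(usable)
  if (n < k) stop("protocol error: fewer usable blocks (", n, ") than folds")
  if (length(unique(usable$ground_truth)) < 2L)
    stop("degenerate-training error: single-class subject")
  set.seed(protocol_seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  predicted <- character(n)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    if (length(test_idx) == 0L) next
    train <- usable[-test_idx, , drop = FALSE]
    model <- train_forest(train, train$ground_truth, config)
    predicted[test_idx] <- predict_forest(model, usable[test_idx, , drop = FALSE])
  }
  usable$predicted <- predicted
  usable$correct <- usable$predicted == usable$ground_truth
  structure(list(protocol = "intra_10fold", method = method,
                 accuracy = weighted_accuracy(usable$correct, usable$block_size),
                 predictions = usable),
            class = "protocol_result")
}

#' Inter-subject leave-one-subject-out evaluation
#'
#' For each subject, a forest is trained on the pooled blocks of every other
#' subject (raw pooling, no per-subject normalization) and evaluated on the
#' held-out subject. Groups (control vs amputee) must be evaluated
#' separately: a mixed-group cohort is refused.
#'
#' @param cohort named list of labelled per-subject feature tables.
#' @param method `"fixed"` or `"variable"`.
#' @param config a [forest_config()].
#' @param groups optional character vector of group memberships parallel to
#'   `cohort`; if given, all entries must be equal.
#' @param purity_cutoff fixed-method mixed-block cutoff.
#' @return named list of `protocol_result` objects, one per held-out
#'   subject (`protocol = "inter_loso"`).
#' @export
run_inter_subject <- function(cohort, method = c("fixed", "variable"),
                              config = forest_config(), groups = NULL,
                              purity_cutoff = 0.95) {
  method <- match.arg(method)
  if (length(cohort) < 2L)
    stop("protocol error: leave-one-subject-out needs at least 2 subjects")
  if (!is.null(groups) && length(unique(groups)) > 1L)
    stop("protocol error: cohort mixes groups; evaluate groups separately")
  usable <- lapply(cohort, .usable_blocks, method = method,
                   purity_cutoff = purity_cutoff)
  out <- vector("list", length(cohort))
  names(out) <- names(cohort)
  for (i in seq_along(cohort)) {
    train <- do.call(rbind, usable[-i])
    test <- usable[[i]]
    if (nrow(test) == 0L) stop("protocol error: no usable blocks for subject ",
                               names(cohort)[i])
    model <- train_forest(train, train$ground_truth, config)
    test$predicted <- predict_forest(model, test)
    test$correct <- test$predicted == test$ground_truth
    out[[i]] <- structure(
      list(protocol = "inter_loso", method = method,
           accuracy = weighted_accuracy(test$correct, test$block_size),
           predictions = test),
      class = "protocol_result")
  }
  out
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %s / %s: accuracy %.4f over %d blocks\n",
              x$protocol, x$method, x$accuracy, nrow(x$predictions)))
  invisible(x)
}
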