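#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive sample outscores a
#' randomly chosen negative one, with ties counted one half. Computed from
#' midranks, which is exactly the normalised Mann-Whitney U statistic.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels: logical, 0/1, or a two-level factor whose
#'   second level is the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), length(scores) > 0)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("factor labels must have two levels", call. = FALSE)
    pos <- labels == levels(labels)[2]
  } else {
    pos <- as.logical(labels)
  }
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Stratified fold assignment: within each class, shuffle and deal samples
# round-robin, so per-fold class counts differ by at most one.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated gradient-boosted prediction of condition labels
#'
#' Fits gradient-boosted decision trees (binary logistic objective) on the
#' expression of a feature gene set and evaluates them by repeated
#' stratified k-fold cross-validation: each round draws a fresh seeded fold
#' partition; each held-out fold contributes one AUC and one
#' misclassification error (probability threshold 0.5).
#'
#' @param expr Expression matrix, genes x samples.
#' @param labels Condition label per sample (two-level factor or coercible;
#'   the second level is the positive class).
#' @param features Character vector of feature gene ids (must be rows of
#'   `expr`), or a list `list(name =, genes =)`.
#' @param rounds Cross-validation rounds (default 10).
#' @param folds Folds per round (default 5).
#' @param seed Integer seed (fold partitions use per-round sub-streams).
#' @param nrounds,max_depth,eta Booster hyperparameters (defaults 100 trees,
#'   depth 4, learning rate 0.1 - moderate values favouring determinism and
#'   desk-scale runtime over tuning).
#' @return Object of class `"prediction_report"`: list with `per_fold`
#'   (data frame: round, fold, auc, error), `mean_auc`, `sd_auc`,
#'   `mean_error`, `sd_error`, `rounds`, `folds`, `seed`, `feature_set`,
#'   `n_features`.
#' @export
cross_validated_boosting <- function(expr, labels, features, rounds = 10,
                                     folds = 5, seed = 1L, nrounds = 100,
                                     max_depth = 4, eta = 0.1) {
  stopifnot(is.matrix(expr))
  set_name <- "features"
  if (is.list(features)) {
    set_name <- features$name %||% "features"
    features <- features$genes
  }
  features <- unique(as.character(features))
  if (length(features) == 0) stop("empty feature set", call. = FALSE)
  missing <- setdiff(features, rownames(expr))
  if (length(missing) > 0) {
    stop("feature gene(s) missing from the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- check_condition(labels, expr)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels", call. = FALSE)
  y <- as.integer(labels == levels(labels)[2])
  if (min(table(y)) < folds) {
    stop("need at least `folds` samples in each class for stratified CV", call. = FALSE)
  }
  x <- t(expr[features, , drop = FALSE])
  per_fold <- vector("list", rounds * folds)
  row <- 0L
  for (r in seq_len(rounds)) {
    fold <- with_substream(seed, sprintf("cv-round%d", r), stratified_folds(y, folds))
    for (f in seq_len(folds)) {
      test <- fold == f
      booster <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, nthread = 1),
        data = xgboost::xgb.DMatrix(x[!test, , drop = FALSE], label = y[!test]),
        nrounds = nrounds, verbose = 0)
      prob <- stats::predict(booster, xgboost::xgb.DMatrix(x[test, , drop = FALSE]))
      row <- row + 1L
      per_fold[[row]] <- data.frame(
        round = r, fold = f,
        auc = auc(prob, y[test]),
        error = mean((prob > 0.5) != y[test]))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  structure(list(per_fold = per_fold,
                 mean_auc = mean(per_fold$auc), sd_auc = stats::sd(per_fold$auc),
                 mean_error = mean(per_fold$error), sd_error = stats::sd(per_fold$error),
                 rounds = rounds, folds = folds, seed = seed,
                 feature_set = set_name, n_features = length(features)),
            class = "prediction_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Prediction report [%s, %d gene(s)]: %d x %d-fold CV\n",
              x$feature_set, x$n_features, x$rounds, x$folds))
  cat(sprintf("  mean AUC  %.3f (+/- %.3f)\n  mean error %.3f (+/- %.3f)\n",
              x$mean_auc, x$sd_auc, x$mean_error, x$sd_error))
  invisible(x)
}
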