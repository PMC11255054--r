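# Combined-metric classification: AUC/p candidate filter, recursive feature
# elimination to five features, gradient-boosted trees with stratified
# tenfold cross-validation, and per-case prediction with cohort overlay.

default_gbm_params <- function() {
  list(nrounds = 100, max_depth = 3, eta = 0.1, subsample = 1.0,
       objective = "binary:logistic")
}

#' Filter candidate features on AUC and p value
#'
#' Keeps features with cross-validated `auc_mean` strictly above `auc_min`
#' and raw Mann-Whitney p strictly below `p_max`.
#'
#' @param stat_rows Output of [feature_group_stats()].
#' @param auc_min,p_max Thresholds (strict inequalities).
#' @return Character vector of feature names.
#' @export
filter_candidates <- function(stat_rows, auc_min = 0.8, p_max = 0.005) {
  keep <- stat_rows$auc_mean > auc_min & stat_rows$p_raw < p_max
  if (!any(keep)) {
    pq_stop("pq_empty_candidate_set",
            "no feature passed AUC > %g and p < %g", auc_min, p_max)
  }
  stat_rows$feature[keep]
}

# deterministic single xgboost fit (single thread, fixed seed)
fit_gbm <- function(x, y, params, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = params$objective, max_depth = params$max_depth,
                  eta = params$eta, subsample = params$subsample,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
}

gbm_predict <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
}

# mean accuracy over an inner stratified CV (RFE scoring); returns the
# fold mean and its standard error
cv_accuracy <- function(x, y, labels, k, seed, params) {
  fold <- stratified_folds(labels, k, seed)
  accs <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test <- fold == f
    if (length(unique(y[!test])) < 2 || length(unique(y[test])) < 2) {
      pq_stop("pq_stratification_error", "fold %d lacks one of the classes", f)
    }
    mod <- fit_gbm(x[!test, , drop = FALSE], y[!test], params, seed + f)
    pred <- gbm_predict(mod, x[test, , drop = FALSE]) >= 0.5
    accs[f] <- mean(pred == (y[test] == 1))
  }
  c(mean = mean(accs), se = stats::sd(accs) / sqrt(k))
}

cohort_matrix <- function(cohort, features, positive) {
  miss <- setdiff(features, names(cohort))
  pq_check(length(miss) == 0, "pq_param_error",
           "missing feature column(s): %s", paste(miss, collapse = ", "))
  x <- as.matrix(cohort[, features, drop = FALSE])
  pq_check(!anyNA(x), "pq_param_error", "feature columns contain NA")
  y <- as.numeric(cohort$class == positive)
  list(x = x, y = y)
}

#' Recursive feature elimination to the top five features
#'
#' Starting from the candidate set, repeatedly removes the feature whose
#' removal maximizes the mean accuracy of the boosted classifier under an
#' inner stratified 5-fold cross-validation, until five remain. Removals
#' scoring within one standard error of the best are treated as equivalent
#' and resolved by dropping the feature with the weakest marginal
#' discrimination (rank AUC), a one-standard-error rule that keeps the
#' elimination from chasing fold noise. With five or fewer candidates the
#' set is passed through unchanged (with a warning attribute).
#'
#' @param cohort Cohort data frame (`class` + feature columns).
#' @param candidates Candidate feature names.
#' @param seed Seed controlling folds and fits.
#' @param n_keep Target number of features.
#' @param inner_k Inner CV folds for the accuracy score.
#' @param params Gradient-boosting hyperparameters.
#' @param positive Positive-class label.
#' @return Character vector of selected features (attribute `passthrough`
#'   set when no elimination was possible).
#' @export
rfe_top5 <- function(cohort, candidates, seed = 1, n_keep = 5, inner_k = 5,
                     params = default_gbm_params(),
                     positive = "oligodendroglioma") {
  if (length(candidates) <= n_keep) {
    return(structure(candidates, passthrough = TRUE))
  }
  cm <- cohort_matrix(cohort, candidates, positive)
  current <- sort(candidates, method = "radix")
  # marginal discrimination, used only to break score ties deterministically
  marginal <- vapply(current, function(f)
    abs(rank_auc(cm$x[, f], cm$y == 1) - 0.5), numeric(1))
  while (length(current) > n_keep) {
    scores <- vapply(current, function(drop_f) {
      sub <- setdiff(current, drop_f)
      cv_accuracy(cm$x[, sub, drop = FALSE], cm$y, cohort$class,
                  inner_k, seed, params)
    }, numeric(2))
    best <- which.max(scores["mean", ])
    tied <- current[scores["mean", ] >=
                      scores["mean", best] - scores["se", best] - 1e-12]
    drop_f <- tied[which.min(marginal[tied])]
    current <- setdiff(current, drop_f)
  }
  current
}

#' Train and evaluate the gradient-boosted classifier
#'
#' Stratified tenfold cross-validation of a gradient-boosted tree
#' classifier (100 trees, depth 3, learning rate 0.1, no subsampling) on
#' the selected features; reports per-fold held-out AUCs, their mean, SD
#' and normal-approximation CI, gain-based feature importances averaged
#' over folds and normalized to sum one, and a final model refit on all
#' rows for prediction. Features are canonicalized to alphabetical order so
#' column permutations of the input cannot change the result.
#'
#' @param cohort Cohort data frame (`class` + feature columns).
#' @param features The selected feature names.
#' @param k Folds.
#' @param seed Seed (folds and fits).
#' @param params Gradient-boosting hyperparameters.
#' @param positive Positive-class label.
#' @return A list of class `classifier_report`: `features`, `importances`,
#'   `fold_aucs`, `auc_mean`, `auc_sd`, `auc_ci95`, `auc_pooled`,
#'   `best_fold_auc`, `seed`, `hyperparameters`, `model`, `cohort_stats`.
#' @export
train_eval_gbm <- function(cohort, features, k = 10, seed = 1,
                           params = default_gbm_params(),
                           positive = "oligodendroglioma") {
  features <- sort(features, method = "radix")
  cm <- cohort_matrix(cohort, features, positive)
  fold <- stratified_folds(cohort$class, k, seed)
  fold_aucs <- rep(NA_real_, k)
  pooled <- rep(NA_real_, nrow(cm$x))
  imp <- stats::setNames(rep(0, length(features)), features)
  for (f in seq_len(k)) {
    test <- fold == f
    if (length(unique(cm$y[test])) < 2 || length(unique(cm$y[!test])) < 2) {
      pq_stop("pq_stratification_error", "fold %d lacks one of the classes", f)
    }
    mod <- fit_gbm(cm$x[!test, , drop = FALSE], cm$y[!test], params, seed + f)
    pred <- gbm_predict(mod, cm$x[test, , drop = FALSE])
    fold_aucs[f] <- rank_auc(pred, cm$y[test] == 1)
    pooled[test] <- pred
    it <- xgboost::xgb.importance(model = mod)
    imp[it$Feature] <- imp[it$Feature] + it$Gain
  }
  imp <- imp / sum(imp)
  m <- mean(fold_aucs)
  s <- stats::sd(fold_aucs)
  final <- fit_gbm(cm$x, cm$y, params, seed)

  # per-feature whisker stats per class, for new-case overlays
  cohort_stats <- do.call(rbind, lapply(features, function(fn) {
    do.call(rbind, lapply(unique(cohort$class), function(cl) {
      v <- cohort[[fn]][cohort$class == cl]
      data.frame(feature = fn, class = cl, min = min(v),
                 q1 = stats::quantile(v, 0.25, names = FALSE),
                 median = stats::median(v),
                 q3 = stats::quantile(v, 0.75, names = FALSE), max = max(v))
    }))
  }))

  structure(list(
    features = features,
    importances = sort(imp, decreasing = TRUE),
    fold_aucs = fold_aucs, auc_mean = m, auc_sd = s,
    auc_ci95 = pmin(pmax(m + c(-1, 1) * 1.96 * s / sqrt(k), 0), 1),
    auc_pooled = rank_auc(pooled, cm$y == 1),
    best_fold_auc = max(fold_aucs), seed = seed,
    hyperparameters = params, positive = positive,
    model = final, cohort_stats = cohort_stats),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Gradient-boosted classifier on %d features (positive: %s)\n",
              length(x$features), x$positive))
  cat(sprintf("  CV AUC %.3f +/- %.3f (95%% CI %.3f-%.3f), best fold %.3f\n",
              x$auc_mean, x$auc_sd, x$auc_ci95[1], x$auc_ci95[2],
              x$best_fold_auc))
  cat("  importances:",
      paste(sprintf("%s (%.3f)", names(x$importances), x$importances),
            collapse = ", "), "\n")
  invisible(x)
}

#' Predict the class probability of a new case
#'
#' @param report A `classifier_report` from [train_eval_gbm()].
#' @param feature_vector One-row data frame (or named vector/list)
#'   containing at least the report's features.
#' @return A list with `probability` (of the positive class) and `overlay`
#'   (per feature: the case value plus the training cohort's per-class
#'   min/q1/median/q3/max whisker statistics).
#' @export
predict_case <- function(report, feature_vector) {
  fv <- as.list(feature_vector)
  miss <- setdiff(report$features, names(fv))
  if (length(miss) > 0) {
    pq_stop("pq_param_error", "missing feature column(s): %s",
            paste(miss, collapse = ", "))
  }
  x <- matrix(as.numeric(fv[report$features]), nrow = 1,
              dimnames = list(NULL, report$features))
  prob <- gbm_predict(report$model, x)
  overlay <- report$cohort_stats
  overlay$case_value <- as.numeric(fv[overlay$feature])
  list(probability = unname(prob), overlay = overlay)
}
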