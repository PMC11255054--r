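# Two-group feature statistics: Mann-Whitney U, cross-validated per-feature
# AUC-ROC, DeLong AUC comparison, Bonferroni correction, Spearman
# correlation and Youden-optimal operating points.
#
# The positive class is the oligodendroglioma throughout (higher nrCBV,
# lower PSR).

#' Mann-Whitney U test
#'
#' Two-sided p value, exact for small tie-free samples and otherwise by the
#' normal approximation with tie and continuity correction; the U statistic
#' is reported for the first group.
#'
#' @param a,b Numeric value vectors for the two groups.
#' @return A list with `u` and `p`.
#' @export
mann_whitney <- function(a, b) {
  pq_check(length(a) >= 3 && length(b) >= 3, "pq_param_error",
           "each group needs at least 3 values")
  wt <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  list(u = unname(wt$statistic), p = wt$p.value)
}

# rank-based (Mann-Whitney) AUC of score for label==positive
rank_auc <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated AUC-ROC of a single feature
#'
#' Stratified k-fold scheme: in each fold the feature's orientation (whether
#' high values score as the positive class) is chosen on the training
#' portion (flipped if the training AUC is below 0.5), and the AUC is then
#' computed on the held-out portion. Returns the mean and SD over folds and
#' a normal-approximation CI `mean +/- 1.96 * SD / sqrt(k)` clipped to
#' \[0, 1\], plus the pooled out-of-fold AUC for transparency.
#'
#' @param values Feature values.
#' @param labels Class labels; `positive` names the positive class.
#' @param k Number of folds.
#' @param seed Seed for the fold assignment.
#' @param positive Positive-class label.
#' @return A list with `auc_mean`, `auc_sd`, `ci95`, `fold_aucs`,
#'   `auc_pooled`.
#' @export
cv_feature_auc <- function(values, labels, k = 10, seed = 1,
                           positive = "oligodendroglioma") {
  pos <- labels == positive
  pq_check(length(values) >= 2 * k, "pq_stratification_error",
           "need at least 2k observations for %d stratified folds", k)
  fold <- stratified_folds(labels, k, seed)
  fold_aucs <- rep(NA_real_, k)
  pooled_score <- rep(NA_real_, length(values))
  for (f in seq_len(k)) {
    test <- fold == f
    if (length(unique(pos[test])) < 2 || length(unique(pos[!test])) < 2) {
      pq_stop("pq_stratification_error",
              "fold %d lacks one of the classes", f)
    }
    flip <- rank_auc(values[!test], pos[!test]) < 0.5
    score <- if (flip) -values else values
    fold_aucs[f] <- rank_auc(score[test], pos[test])
    pooled_score[test] <- score[test]
  }
  m <- mean(fold_aucs)
  s <- stats::sd(fold_aucs)
  ci <- pmin(pmax(m + c(-1, 1) * 1.96 * s / sqrt(k), 0), 1)
  list(auc_mean = m, auc_sd = s, ci95 = ci, fold_aucs = fold_aucs,
       auc_pooled = rank_auc(pooled_score, pos))
}

#' Paired comparison of two features' AUCs (DeLong Z-test)
#'
#' @param values1,values2 Two features measured on the same subjects.
#' @param labels Class labels; `positive` as in [cv_feature_auc()].
#' @param positive Positive-class label.
#' @return A list with `z` and `p` (two-sided).
#' @export
compare_auc <- function(values1, values2, labels,
                        positive = "oligodendroglioma") {
  pq_check(length(values1) == length(values2) &&
             length(values1) == length(labels), "pq_param_error",
           "values and labels must have equal length")
  pq_check(stats::sd(values1) > 0 && stats::sd(values2) > 0,
           "pq_param_error", "constant feature in AUC comparison")
  if (identical(values1, values2)) return(list(z = 0, p = 1))
  resp <- factor(ifelse(labels == positive, "pos", "neg"),
                 levels = c("neg", "pos"))
  # orient each feature so its AUC >= 0.5 before the paired test
  orient <- function(v) if (rank_auc(v, resp == "pos") < 0.5) -v else v
  r1 <- pROC::roc(resp, orient(values1), quiet = TRUE, direction = "<")
  r2 <- pROC::roc(resp, orient(values2), quiet = TRUE, direction = "<")
  tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  list(z = unname(tst$statistic), p = tst$p.value)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with family size `m` (defaulting to the 44
#' computed summary values: 22 per metric for two metrics).
#'
#' @param p_values Raw p values.
#' @param m Family size; must be at least `length(p_values)`.
#' @return Adjusted p values.
#' @export
bonferroni_adjust <- function(p_values, m = 44) {
  pq_check(m >= length(p_values), "pq_param_error",
           "family size m (%d) smaller than number of tests (%d)",
           m, length(p_values))
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Pairwise Spearman correlation matrix
#'
#' Rank correlation with average ranks for ties; p values from the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))`. Constant columns give
#' `NA` entries.
#'
#' @param feature_table Data frame or matrix of numeric feature columns.
#' @return A list with matrices `rho` and `p`.
#' @export
spearman_matrix <- function(feature_table) {
  x <- as.matrix(feature_table)
  pq_check(nrow(x) >= 5, "pq_param_error", "need at least 5 subjects")
  keep_sd <- apply(x, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[keep_sd == 0, ] <- NA_real_
  rho[, keep_sd == 0] <- NA_real_
  n <- nrow(x)
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(rho) >= 1] <- 0
  diag(p) <- NA_real_
  list(rho = rho, p = p)
}

#' Youden-optimal threshold with sensitivity/specificity/accuracy
#'
#' Scans all midpoints between consecutive sorted unique values, maximizing
#' `J = sensitivity + specificity - 1`; the orientation (whether the
#' positive class lies above or below the threshold) is chosen so J >= 0,
#' and ties are broken toward higher specificity. Sensitivity is defined on
#' the positive (oligodendroglioma) class.
#'
#' @param values Feature values.
#' @param labels Class labels.
#' @param positive Positive-class label.
#' @return A list with `threshold`, `direction` (`">"` means positive class
#'   above threshold), `sensitivity`, `specificity`, `accuracy`, `youden_j`.
#' @export
youden_threshold <- function(values, labels,
                             positive = "oligodendroglioma") {
  pos <- labels == positive
  pq_check(any(pos) && any(!pos), "pq_param_error",
           "both classes must be present")
  u <- sort(unique(values))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  best <- list(j = -Inf, spec = -Inf)
  for (thr in cand) {
    for (dir in c(">", "<")) {
      pred_pos <- if (dir == ">") values > thr else values < thr
      sens <- mean(pred_pos[pos])
      spec <- mean(!pred_pos[!pos])
      j <- sens + spec - 1
      if (j > best$j + 1e-12 ||
          (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
        best <- list(j = j, thr = thr, dir = dir, sens = sens, spec = spec)
      }
    }
  }
  acc <- {
    pred_pos <- if (best$dir == ">") values > best$thr else values < best$thr
    mean(pred_pos == pos)
  }
  list(threshold = best$thr, direction = best$dir, sensitivity = best$sens,
       specificity = best$spec, accuracy = acc, youden_j = best$j)
}

#' Per-feature group statistics table
#'
#' For every feature column: group means and SDs, Mann-Whitney U and raw /
#' Bonferroni-adjusted p values, cross-validated AUC (mean, SD, CI), and the
#' Youden-optimal threshold with its sensitivity, specificity and accuracy.
#'
#' @param cohort A data frame with a `class` column and feature columns.
#' @param features Feature column names (default: all 44 canonical names
#'   present).
#' @param k CV folds for the per-feature AUC.
#' @param seed Fold seed.
#' @param m Bonferroni family size.
#' @param positive Positive-class label.
#' @return A data frame with one row per feature.
#' @export
feature_group_stats <- function(cohort, features = NULL, k = 10, seed = 1,
                                m = 44, positive = "oligodendroglioma") {
  if (is.null(features)) {
    features <- intersect(feature_names(), names(cohort))
  }
  pq_check(length(features) > 0, "pq_param_error", "no feature columns found")
  pos <- cohort$class == positive
  pq_check(sum(pos) >= 3 && sum(!pos) >= 3 && nrow(cohort) >= 2 * k,
           "pq_stratification_error",
           "cohort too small for stratified %d-fold statistics (%d vs %d)",
           k, sum(pos), sum(!pos))
  rows <- lapply(features, function(f) {
    v <- cohort[[f]]
    mw <- mann_whitney(v[pos], v[!pos])
    cv <- cv_feature_auc(v, cohort$class, k = k, seed = seed,
                         positive = positive)
    yd <- youden_threshold(v, cohort$class, positive = positive)
    data.frame(feature = f,
               mean_pos = mean(v[pos]), sd_pos = stats::sd(v[pos]),
               mean_neg = mean(v[!pos]), sd_neg = stats::sd(v[!pos]),
               u_stat = mw$u, p_raw = mw$p,
               auc_mean = cv$auc_mean, auc_sd = cv$auc_sd,
               auc_ci_lo = cv$ci95[1], auc_ci_hi = cv$ci95[2],
               auc_pooled = cv$auc_pooled,
               youden_threshold = yd$threshold,
               sensitivity = yd$sensitivity, specificity = yd$specificity,
               accuracy = yd$accuracy)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p_raw, m = max(m, nrow(out)))
  out
}
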