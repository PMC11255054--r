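# Nonparametric group statistics and their independent oracles.

# exact permutation oracle for the two-sided Mann-Whitney p value
mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * (n - n1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-9)
}

test_that("Mann-Whitney U agrees with exact permutation enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(mw_exact(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_lt(abs(r$p - 0.1), 0.02)

  # identical multisets: no separation
  expect_gte(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 0.99)

  # oracle sweep over all group sizes <= 7 (tie-free draws)
  set.seed(12)
  for (n1 in 3:7) {
    for (n2 in 3:7) {
      a <- rnorm(n1)
      b <- rnorm(n2, mean = runif(1, -1.5, 1.5))
      expect_lt(abs(mann_whitney(a, b)$p - mw_exact(a, b)), 0.02)
    }
  }

  # invariance under swapping groups
  a <- rnorm(6)
  b <- rnorm(5, 1)
  expect_equal(mann_whitney(a, b)$p, mann_whitney(b, a)$p)
})

test_that("cross-validated per-feature AUC behaves as a rank statistic", {
  lab <- rep(c("astrocytoma", "oligodendroglioma"), each = 26)

  # perfect separation
  v <- c(rnorm(26, 0, 0.1), rnorm(26, 10, 0.1))
  r <- cv_feature_auc(v, lab, seed = 3)
  expect_equal(r$auc_mean, 1.0)

  # feature independent of the label
  set.seed(4)
  lab2k <- rep(c("astrocytoma", "oligodendroglioma"), each = 1000)
  r0 <- cv_feature_auc(rnorm(2000), lab2k, seed = 5)
  expect_gt(r0$auc_mean, 0.45)
  expect_lt(r0$auc_mean, 0.55)

  # orientation handles label inversion
  set.seed(6)
  v <- rnorm(52) + (lab == "oligodendroglioma") * 1.5
  inv <- ifelse(lab == "astrocytoma", "oligodendroglioma", "astrocytoma")
  r1 <- cv_feature_auc(v, lab, seed = 7)
  r2 <- cv_feature_auc(v, inv, seed = 7)
  expect_lt(abs(r1$auc_mean - r2$auc_mean), 0.02)

  # invariance under strictly monotone transforms
  r3 <- cv_feature_auc(exp(3 * v), lab, seed = 7)
  expect_identical(r1$fold_aucs, r3$fold_aucs)

  expect_error(cv_feature_auc(rnorm(10), rep(c("a", "b"), 5), k = 10),
               class = "pq_stratification_error")
})

test_that("DeLong Z-test separates informative from noise features", {
  lab <- rep(c("astrocytoma", "oligodendroglioma"), each = 100)
  id <- rnorm(200)
  r <- compare_auc(id, id, lab)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  set.seed(9)
  good <- rnorm(200) + (lab == "oligodendroglioma") * 6
  noise <- rnorm(200)
  expect_lt(compare_auc(good, noise, lab)$p, 0.001)

  # paired-bootstrap oracle on a small instance
  set.seed(10)
  lab40 <- rep(c("astrocytoma", "oligodendroglioma"), each = 30)
  f1 <- rnorm(60) + (lab40 == "oligodendroglioma") * 1.4
  f2 <- rnorm(60) + (lab40 == "oligodendroglioma") * 0.5
  d_obs <- compare_auc(f1, f2, lab40)
  pos <- lab40 == "oligodendroglioma"
  boot_d <- replicate(4000, {
    idx <- c(sample(which(pos), replace = TRUE),
             sample(which(!pos), replace = TRUE))
    a1 <- perfquant:::rank_auc(f1[idx], pos[idx])
    a2 <- perfquant:::rank_auc(f2[idx], pos[idx])
    a1 - a2
  })
  p_boot <- 2 * min(mean(boot_d <= 0), mean(boot_d >= 0))
  expect_lt(abs(d_obs$p - p_boot), 0.03)
})

test_that("Bonferroni adjustment is capped, monotone and idempotent at cap", {
  expect_equal(bonferroni_adjust(0.0005, m = 44), 0.022)
  expect_equal(bonferroni_adjust(0.5, m = 44), 1)
  expect_equal(bonferroni_adjust(1 / 44, m = 44), 1)
  p <- runif(10)
  expect_true(all(bonferroni_adjust(p, m = 44) >= p))
  expect_error(bonferroni_adjust(runif(50), m = 44),
               class = "pq_param_error")
})

test_that("Spearman matrix matches rank-then-Pearson", {
  x <- 1:20
  tab <- data.frame(a = x, b = 2 * x, c = -x^3, d = rnorm(20))
  r <- spearman_matrix(tab)
  expect_equal(r$rho["a", "b"], 1)
  expect_equal(r$rho["a", "c"], -1)
  expect_equal(r$rho["a", "d"],
               cor(rank(tab$a), rank(tab$d)), tolerance = 1e-12)

  set.seed(14)
  tab2 <- as.data.frame(matrix(rnorm(120), 20))
  r2 <- spearman_matrix(tab2)
  oracle <- cor(apply(tab2, 2, rank))
  expect_equal(unname(r2$rho), unname(oracle), tolerance = 1e-12)

  tab$e <- 5
  expect_true(all(is.na(spearman_matrix(tab)$rho[, "e"])))
})

test_that("Youden threshold matches an exhaustive scan and reproduces", {
  lab6 <- c(rep("astrocytoma", 3), rep("oligodendroglioma", 3))
  r <- youden_threshold(c(1, 2, 3, 7, 8, 9), lab6)
  expect_gt(r$threshold, 3)
  expect_lt(r$threshold, 7)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$accuracy, 1)

  # constant values: J = 0, sens + spec = 1
  rc <- youden_threshold(rep(2, 6), lab6)
  expect_equal(rc$youden_j, 0)
  expect_equal(rc$sensitivity + rc$specificity, 1)

  # oracle: exhaustive threshold scan on random data
  set.seed(15)
  for (rep in 1:10) {
    v <- rnorm(30)
    lab <- sample(rep(c("astrocytoma", "oligodendroglioma"), 15))
    r <- youden_threshold(v, lab)
    pos <- lab == "oligodendroglioma"
    best_j <- max(sapply(sort(v), function(t0) {
      max(mean(v[pos] > t0) + mean(v[!pos] <= t0),
          mean(v[pos] < t0) + mean(v[!pos] >= t0)) - 1
    }))
    expect_equal(r$youden_j, best_j, tolerance = 1e-9)

    # reapplying the reported threshold reproduces sens/spec exactly
    pred_pos <- if (r$direction == ">") v > r$threshold else v < r$threshold
    expect_equal(mean(pred_pos[pos]), r$sensitivity)
    expect_equal(mean(!pred_pos[!pos]), r$specificity)
  }
})

test_that("the per-feature statistics table is complete and coherent", {
  tab <- sim_feature_cohort(11, 60, seed = 2)
  st <- feature_group_stats(tab, k = 10, seed = 3)
  expect_equal(nrow(st), 44)
  expect_true(all(st$p_bonferroni >= st$p_raw))
  expect_true(all(st$auc_mean >= 0 & st$auc_mean <= 1))
  expect_true(all(st$sensitivity >= 0 & st$sensitivity <= 1))
  expect_true(all(st$specificity >= 0 & st$specificity <= 1))
  # oligodendrogliomas have higher CBV and lower PSR on the mean features
  expect_gt(st$mean_pos[st$feature == "nrCBV_mean"],
            st$mean_neg[st$feature == "nrCBV_mean"])
  expect_lt(st$mean_pos[st$feature == "PSR_mean"],
            st$mean_neg[st$feature == "PSR_mean"])
})
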