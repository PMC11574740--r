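test_that("feature assembly yields 135 aligned, named columns", {
  set.seed(1)
  ids <- sprintf("sub-%02d", 1:8)
  rn <- function(m) { rownames(m) <- ids; m }
  lv <- rn(matrix(rpois(8 * 15, 3), 8, 15,
                  dimnames = list(NULL, ptemarkers:::usc_lobe_names)))
  cz <- rn(matrix(rnorm(8 * 105), 8, 105,
                  dimnames = list(NULL, paste0("conn_", 1:105))))
  al <- rn(matrix(rnorm(8 * 15), 8, 15,
                  dimnames = list(NULL, ptemarkers:::usc_lobe_names)))
  labels <- data.frame(subject_id = ids,
                       group = rep(c("PTE", "nonPTE"), 4))
  ft <- assemble_features(lv, cz, al, labels)
  expect_equal(ncol(ft$x), 135)
  expect_equal(as.vector(table(ft$feature_group)[c("lesion", "connectivity",
                                                 "alff")]),
               c(15L, 105L, 15L))
  expect_equal(ft$feature_group[1:15], rep("lesion", 15))
  # shuffled input rows align back by id
  sh <- sample(8)
  ft2 <- assemble_features(lv[sh, ], cz, al[rev(sh), ], labels)
  expect_equal(ft$x, ft2$x)
  # a missing subject is named in the error
  expect_error(assemble_features(lv[-3, ], cz, al, labels), ids[3])
})

test_that("nested CV satisfies the leave-one-pair-out fold contract", {
  ft <- toy_features(5, 8, effect = 2, seed = 2)
  cfg <- cv_config(method = "svm", n_repeats = 2, pca_grid = 3,
                   cost_grid = 1, seed = 3)
  cv <- nested_cv_auc(ft, cfg)
  # every subject scored exactly once per repeat (pairs partition the data)
  expect_true(all(!is.na(cv$scores)))
  expect_equal(dim(cv$scores), c(10, 2))
  expect_true(all(cv$auc_samples >= 0 & cv$auc_samples <= 1))
  expect_equal(nrow(cv$chosen), 5)  # one hyperparameter row per outer fold
  # unbalanced labels are rejected
  bad <- ft; bad$labels[1] <- "nonPTE"
  expect_error(nested_cv_auc(bad, cfg), "balanced")
})

test_that("separable features reach AUC 1 and null features stay near 0.5", {
  cfg <- cv_config(method = "svm", n_repeats = 3, pca_grid = c(3, 5),
                   cost_grid = 1, seed = 4)
  sep <- toy_features(8, 12, effect = 6, seed = 5)
  expect_equal(nested_cv_auc(sep, cfg)$mean, 1.0)
  nul <- toy_features(8, 12, effect = 0, seed = 6)
  cfg$n_repeats <- 10L
  expect_lt(abs(nested_cv_auc(nul, cfg)$mean - 0.5), 0.25)
})

test_that("no-leakage: the held-out pair never influences its own fit", {
  # recompute one outer fold by deleting the test rows up front: identical
  ft <- toy_features(4, 6, effect = 1, seed = 7)
  cfg <- cv_config(method = "svm", n_repeats = 1, pca_grid = 3,
                   cost_grid = 1, seed = 8)
  test_idx <- c(1, 5)
  train_idx <- setdiff(seq_len(8), test_idx)
  fit1 <- ptemarkers:::tune_and_fit(ft$x[train_idx, ], ft$labels[train_idx],
                                    cfg, 99L)
  sub <- ft$x[train_idx, ]
  fit2 <- ptemarkers:::tune_and_fit(sub, ft$labels[train_idx], cfg, 99L)
  expect_identical(fit1$score(ft$x[test_idx, ]), fit2$score(ft$x[test_idx, ]))
})

test_that("all four classifier backends run and separate planted signal", {
  sep <- toy_features(6, 10, effect = 5, seed = 9)
  for (m in c("ksvm", "svm", "rf", "nn")) {
    cfg <- cv_config(method = m, n_repeats = 1, pca_grid = 3, cost_grid = 1,
                     gamma_scale_grid = 1, rf_trees = 100, nn_epochs = 80,
                     seed = 10)
    cv <- nested_cv_auc(sep, cfg)
    expect_gte(cv$mean, 0.9)
  }
})

test_that("permutation null is seeded and centred near one half", {
  ft <- toy_features(6, 8, effect = 0, seed = 11)
  cfg <- cv_config(method = "svm", n_repeats = 2, pca_grid = 3,
                   cost_grid = 1, seed = 12)
  n1 <- permutation_auc_null(ft, cfg, n_null = 30)
  n2 <- permutation_auc_null(ft, cfg, n_null = 30)
  expect_identical(n1$null_auc_samples, n2$null_auc_samples)
  expect_lt(abs(mean(n1$null_auc_samples) - 0.5), 0.1)
  expect_gte(n1$p_value, 0.01)  # no real signal to detect
})

test_that("SVM importance finds a planted informative feature", {
  ft <- toy_features(10, 20, effect = 4, k = 1, seed = 13)
  imp <- svm_feature_importance(ft, cv_config(method = "svm", pca_grid = 8,
                                              cost_grid = 1))
  expect_length(imp$feature_importance, 20)
  expect_equal(unname(which.max(imp$feature_importance)), 1L)
  expect_error(svm_feature_importance(ft, cv_config(method = "rf")),
               "coefficients")
})

test_that("ROI importance aggregates blocks and splits connectivity", {
  set.seed(14)
  ids <- sprintf("sub-%02d", 1:12)
  rn <- function(m) { rownames(m) <- ids; m }
  lv <- rn(matrix(rnorm(12 * 15), 12, 15,
                  dimnames = list(NULL, ptemarkers:::usc_lobe_names)))
  pairs <- ptemarkers:::upper_pairs(15)
  cn <- paste0("conn_", gsub(" ", ".", ptemarkers:::usc_lobe_names[pairs[, 1]]),
               "_", gsub(" ", ".", ptemarkers:::usc_lobe_names[pairs[, 2]]))
  cz <- rn(matrix(rnorm(12 * 105), 12, 105, dimnames = list(NULL, cn)))
  al <- rn(matrix(rnorm(12 * 15), 12, 15,
                  dimnames = list(NULL, ptemarkers:::usc_lobe_names)))
  labels <- data.frame(subject_id = ids,
                       group = rep(c("PTE", "nonPTE"), each = 6))
  lv[labels$group == "PTE", 6] <- lv[labels$group == "PTE", 6] + 5
  ft <- assemble_features(lv, cz, al, labels)
  imp <- svm_feature_importance(ft, cv_config(method = "svm", pca_grid = 10,
                                              cost_grid = 1))
  expect_length(imp$roi_importance, 15)
  expect_length(imp$feature_importance, 135)
  # total ROI mass equals total positive importance (conn split in halves)
  expect_equal(sum(imp$roi_importance), sum(imp$feature_importance))
})

test_that("learning curve grows with n and extrapolates exactly", {
  ft <- toy_features(12, 10, effect = 2.5, seed = 15)
  cfg <- cv_config(method = "svm", n_repeats = 2, pca_grid = 3,
                   cost_grid = 1, seed = 16)
  expect_warning(lc <- learning_curve(ft, cfg, n_grid = c(4, 8, 16, 24),
                                      subsets = 2), "n < 6")
  expect_equal(lc$curve$n, c(8, 16, 24))
  # a planted effect should not lose much AUC as n grows
  expect_gte(lc$curve$mean_auc[3], lc$curve$mean_auc[1] - 0.05)

  # quadratic oracle: planted coefficients recovered to 1e-9
  d <- data.frame(n = seq(10, 70, 10))
  d$mean_auc <- 0.5 + 0.004 * d$n - 0.00002 * d$n^2
  ex <- extrapolate_auc(d, fit_last_k = 6, target_n = 50)
  expect_equal(ex$coefficients, c(0.5, 0.004, -0.00002), tolerance = 1e-9)
  expect_equal(ex$predicted, 0.5 + 0.004 * 50 - 0.00002 * 2500,
               tolerance = 1e-9)
  # three points are interpolated exactly
  ex3 <- extrapolate_auc(d[1:3, ], fit_last_k = 3, target_n = 40)
  expect_equal(max(abs(ex3$residuals)), 0, tolerance = 1e-12)
  # out-of-range predictions clip with a warning
  d2 <- data.frame(n = c(10, 20, 30), mean_auc = c(0.5, 0.6, 0.8))
  expect_warning(exc <- extrapolate_auc(d2, 3, 100), "clipped")
  expect_equal(exc$predicted, 1)
  expect_error(extrapolate_auc(d[1:2, ], 3, 50), "fit_last_k|available")
})
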