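test_that("variance F statistic matches hand computation", {
  a <- matrix(c(-3, 3), 2, 1)
  b <- matrix(c(-1, 1), 2, 1)
  expect_equal(pointwise_variance_f(a, b), 18 / 2)   # s2 = 18 and 2
  expect_equal(pointwise_variance_f(b, a), 1 / 9)    # swap -> reciprocal
  expect_equal(pointwise_variance_f(a, a), 1)
  # zero denominator variance yields the +Inf sentinel
  z <- matrix(c(1, 1), 2, 1)
  expect_equal(pointwise_variance_f(a, z), Inf)
})

test_that("permutation p equals the exhaustive enumeration oracle", {
  a <- matrix(c(-3, 3), 2, 1)
  b <- matrix(c(-1, 1), 2, 1)
  # independent oracle: enumerate all 6 labelings by brute force
  x <- c(-3, 3, -1, 1)
  combs <- combn(4, 2)
  f_all <- apply(combs, 2, function(ia) var(x[ia]) / var(x[-ia]))
  expect_equal(sort(f_all), sort(c(9, 1, 1, 1, 1, 1 / 9)))
  p_oracle <- mean(f_all >= 9)
  expect_equal(p_oracle, 1 / 6)
  sm <- permutation_f_test(a, b, nperm = 1000, seed = 1)
  expect_true(sm$exhaustive)
  expect_equal(sm$p_raw, p_oracle)
})

test_that("sampled permutation p agrees with exhaustive p on small groups", {
  set.seed(4)
  a <- matrix(rnorm(4 * 3), 4, 3)
  b <- matrix(rnorm(4 * 3), 4, 3)
  p_ex <- permutation_f_test(a, b, nperm = 100, seed = 1)$p_raw  # 70 labelings
  p_mc <- permutation_f_test(a, b, nperm = 60, seed = 2)$p_raw   # sampled
  expect_true(all(abs(p_ex - p_mc) < 0.2))
  expect_true(all(p_mc > 0))  # the +1 convention forbids p = 0
  # seeded determinism
  expect_identical(permutation_f_test(a, b, nperm = 60, seed = 5)$p_raw,
                   permutation_f_test(a, b, nperm = 60, seed = 5)$p_raw)
})

test_that("BH step-up matches the hand-worked thresholds", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(bh_fdr(p, 0.05), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(bh_fdr(0.04, 0.05), TRUE)      # m = 1 reduces to raw threshold
  # never rejects more than raw 0.05 thresholding; monotone in q
  set.seed(1)
  pv <- runif(200)^2
  expect_lte(sum(bh_fdr(pv, 0.05)), sum(pv <= 0.05))
  expect_lte(sum(bh_fdr(pv, 0.01)), sum(bh_fdr(pv, 0.05)))
})

test_that("rank-sum test matches exact enumeration and limits", {
  expect_equal(ranksum_test(c(3, 4), c(1, 2)), 1 / 6)   # all ranks on top
  x <- rnorm(10)
  expect_gte(ranksum_test(x, x), 0.5)                   # no one-sided evidence
  set.seed(2)
  expect_lt(ranksum_test(rnorm(20, 10), rnorm(20)), 1e-4)
})

test_that("region table tests lesions and ALFF per ROI with BH", {
  set.seed(8)
  n <- 12
  groups <- rep(c("PTE", "nonPTE"), each = n)
  lv <- matrix(rpois(2 * n * 15, 5), 2 * n, 15,
               dimnames = list(NULL, paste0("roi", 1:15)))
  al <- matrix(rnorm(2 * n * 15), 2 * n, 15,
               dimnames = list(NULL, colnames(lv)))
  # plant a strong ALFF variance effect and lesion burden in ROI 6
  al[groups == "PTE", 6] <- al[groups == "PTE", 6] * 4
  lv[groups == "PTE", 6] <- lv[groups == "PTE", 6] + 30
  tab <- region_tests(lv, al, groups, nperm = 499, seed = 3)
  expect_equal(nrow(tab), 15)
  expect_true(all(tab$p_lesion > 0 & tab$p_lesion <= 1))
  expect_true(all(tab$p_alff > 0 & tab$p_alff <= 1))
  expect_equal(which.min(tab$p_lesion), 6)
  expect_equal(which.min(tab$p_alff), 6)
  expect_true(tab$sig_lesion[6])
})

test_that("voxelwise analysis respects the mask and returns volumes", {
  set.seed(9)
  g <- c(6, 6, 3)
  mask <- array(FALSE, g); mask[2:5, 2:5, ] <- TRUE
  maps <- lapply(1:12, function(i) array(rnorm(prod(g)), g))
  groups <- rep(c("PTE", "nonPTE"), each = 6)
  vx <- voxelwise_group_analysis(maps, groups, mask, nperm = 99, seed = 1)
  expect_true(all(is.na(vx$p_raw[!mask])))
  expect_true(all(vx$p_raw[mask] > 0 & vx$p_raw[mask] <= 1))
  expect_false(any(vx$sig[!mask]))
})

test_that("null region-test calibration stays near the nominal level", {
  # null cohorts: equal prevalence, unit variance ratios, no shifts
  reps <- 30
  rej_les <- rej_alff <- 0
  cfg <- cohort_config(n_per_group = 10, grid_shape = c(20, 20, 8),
                       n_volumes = 64, effect = "null", seed = 1)
  parc <- generate_parcellation(cfg$grid_shape)
  for (r in seq_len(reps)) {
    cfg$seed <- 100 + r
    co <- generate_cohort(cfg)
    groups <- cohort_labels(co)$group
    lv <- t(vapply(co$subjects, function(s)
      roi_lesion_volumes(s$true_lesion_mask, parc), numeric(15)))
    al <- t(vapply(co$subjects, function(s)
      lobe_alff(s$ts, parc, cfg$repetition_interval, cfg$alff_band),
      numeric(15)))
    tab <- region_tests(lv, al, groups, nperm = 199, seed = r)
    rej_les <- rej_les + sum(tab$sig_lesion, na.rm = TRUE)
    rej_alff <- rej_alff + sum(tab$sig_alff, na.rm = TRUE)
  }
  # per-ROI BH rejection rate should sit at or below ~q = 0.05 plus
  # 3 binomial standard errors
  n_tests <- reps * 15
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_tests)
  expect_lte(rej_les / n_tests, bound)
  expect_lte(rej_alff / n_tests, bound)
})
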