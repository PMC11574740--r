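test_that("histogram matching aligns in-mask quantiles to the reference", {
  set.seed(3)
  g <- c(12, 12, 4)
  mask <- array(runif(prod(g)) > 0.3, g)
  v <- array(runif(prod(g)), g); v[!mask] <- 0
  r <- array(rbeta(prod(g), 2, 5), g); r[!mask] <- 0
  m <- histogram_match(v, r, mask)
  qs <- seq(0.1, 0.9, 0.1)
  binw <- 1 / sum(mask)
  expect_equal(unname(quantile(m[mask], qs)), unname(quantile(r[mask], qs)),
               tolerance = 0.05)
  expect_identical(m[!mask], v[!mask])  # background untouched
  # identity: matching a volume to itself returns it (up to quantization)
  mm <- histogram_match(v, v, mask)
  expect_lt(max(abs(mm[mask] - v[mask])), 0.01)
  # rank invariance: a monotone transform matched back recovers the original
  vt <- v; vt[mask] <- v[mask]^3
  back <- histogram_match(vt, v, mask)
  expect_lt(max(abs(back[mask] - v[mask])), 0.01)
  # constant input maps to the reference median
  vc <- array(0.5, g); vc[!mask] <- 0
  expect_message(mc <- histogram_match(vc, r, mask), "median")
  expect_equal(unique(mc[mask]), median(r[mask]))
})

test_that("median filter matches a brute-force oracle", {
  set.seed(4)
  img <- matrix(runif(15 * 13), 15, 13)
  expect_equal(median_filter(img, 3), brute_median_filter(img, 3))
  expect_equal(median_filter(img, 5), brute_median_filter(img, 5))
  # constants pass through
  expect_equal(median_filter(matrix(2, 9, 9), 7), matrix(2, 9, 9))
  # a single hot pixel in a constant field disappears
  hot <- matrix(0, 15, 15); hot[8, 8] <- 5
  expect_equal(median_filter(hot, 7), matrix(0, 15, 15))
  # a 9x9 hot block survives 7x7 filtering in its interior
  blk <- matrix(0, 21, 21); blk[7:15, 7:15] <- 1
  out <- median_filter(blk, 7)
  expect_equal(out[11, 11], 1)
  expect_equal(out, brute_median_filter(blk, 7))
  expect_error(median_filter(img, 4), "odd")
})

test_that("score maps are nonnegative and concentrate on true lesions", {
  fx <- contrast_fixture()
  parc <- fx$parc
  scores <- lapply(seq_along(fx$anats), function(i)
    lesion_score_map(fx$model, fx$anats[[i]])$scores)
  expect_true(all(vapply(scores, function(s) all(s >= 0), TRUE)))
  expect_equal(dim(scores[[1]]), dim(fx$anats[[1]]))
  inm <- parc$mask
  tr <- unlist(lapply(fx$cohort$subjects,
                      function(s) s$true_lesion_mask[inm]))
  sc <- unlist(lapply(scores, function(s) s[inm]))
  expect_gt(mean(sc[tr == 1]), 2 * mean(sc[tr == 0]))
})

test_that("one-class binarization flags only genuine outliers", {
  set.seed(6)
  g <- c(4, 4, 2)
  mask <- array(TRUE, g)
  # all-identical maps: every mask empty (degenerate rule)
  same <- lapply(1:10, function(i) array(1, g))
  expect_true(all(!unlist(binarize_lesions(same, mask))))
  # Gaussian scores, nu = 0.1: per-voxel flagged fraction in [0.02, 0.25]
  maps <- lapply(1:100, function(i) array(rnorm(prod(g)), g))
  masks <- binarize_lesions(maps, mask, nu = 0.1)
  frac <- Reduce(`+`, lapply(masks, function(m) m * 1)) / 100
  expect_true(all(frac >= 0.02 & frac <= 0.25))
  # a planted 10-SD outlier is flagged at its voxel
  maps2 <- lapply(1:20, function(i) array(rnorm(prod(g)), g))
  maps2[[4]][2, 2, 1] <- 10
  m2 <- binarize_lesions(maps2, mask, nu = 0.1)
  expect_true(m2[[4]][2, 2, 1])
  expect_error(binarize_lesions(maps2[1:5], mask), "8 subjects")
})

test_that("binarization is equivariant under subject permutation", {
  set.seed(7)
  g <- c(3, 3, 2)
  mask <- array(TRUE, g)
  maps <- lapply(1:12, function(i) array(rnorm(prod(g)), g))
  m1 <- binarize_lesions(maps, mask)
  perm <- sample(12)
  m2 <- binarize_lesions(maps[perm], mask)
  expect_identical(m1[perm], m2)
})

test_that("ROI lesion volumes count mask voxels per region", {
  parc <- generate_parcellation(c(20, 20, 8))
  empty <- array(FALSE, dim(parc$labels))
  expect_equal(unname(roi_lesion_volumes(empty, parc)), rep(0, 15))
  # the whole of ROI 3
  m3 <- parc$labels == 3
  v <- roi_lesion_volumes(m3, parc)
  expect_equal(unname(v[3]), sum(parc$labels == 3))
  expect_equal(sum(v[-3]), 0)
  # a hand-placed mask straddling ROI 1 (3 voxels) and ROI 2 (2 voxels)
  i1 <- which(parc$labels == 1)[1:3]
  i2 <- which(parc$labels == 2)[1:2]
  ms <- array(FALSE, dim(parc$labels)); ms[c(i1, i2)] <- TRUE
  expect_equal(unname(roi_lesion_volumes(ms, parc))[1:3], c(3, 2, 0))
  # volume conservation: totals equal in-mask voxel count
  set.seed(8)
  mr <- array(runif(prod(dim(parc$labels))) < 0.1, dim(parc$labels))
  expect_equal(sum(roi_lesion_volumes(mr, parc)),
               sum(mr & parc$labels > 0))
})
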