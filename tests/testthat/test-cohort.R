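test_that("parcellation tiles the brain into 15 deterministic regions", {
  p1 <- generate_parcellation(c(24, 24, 10))
  expect_equal(nrow(p1$roi_table), 15)
  expect_true(0 %in% p1$labels)          # background exists
  expect_setequal(unique(p1$labels[p1$labels > 0]), 1:15)
  expect_true(all(tabulate(p1$labels[p1$labels > 0], 15) >= 27))
  # every nonzero label appears in the roi table
  expect_true(all(unique(p1$labels[p1$labels > 0]) %in% p1$roi_table$id))
  p2 <- generate_parcellation(c(24, 24, 10))
  expect_identical(p1$labels, p2$labels)  # deterministic
  expect_error(generate_parcellation(c(6, 6, 4)), "ROI")
})

test_that("anatomy generation is seeded, masked and noise-controlled", {
  cfg <- cohort_config(n_per_group = 2, grid_shape = c(20, 20, 8))
  a1 <- generate_anatomy(cfg, 5L)
  a2 <- generate_anatomy(cfg, 5L)
  expect_identical(a1, a2)               # same seed, same volume
  a3 <- generate_anatomy(cfg, 6L)
  expect_false(identical(a1, a3))
  mask <- generate_parcellation(cfg$grid_shape)$mask
  expect_true(all(a1[!mask] == 0))       # background exactly zero
  expect_true(all(a1 >= 0 & a1 <= 1))
  cfg0 <- cohort_config(n_per_group = 2, grid_shape = c(20, 20, 8),
                        noise_sd = 0)
  expect_identical(generate_anatomy(cfg0, 1L), generate_anatomy(cfg0, 99L))
})

test_that("lesion planting follows per-ROI prevalence", {
  cfg <- cohort_config(n_per_group = 2, grid_shape = c(24, 24, 10))
  parc <- generate_parcellation(cfg$grid_shape)
  anat <- generate_anatomy(cfg, 3L)

  cfg$lesion_prevalence[] <- 0           # null effect: untouched output
  out <- plant_lesions(anat, parc, "PTE", cfg, 3L)
  expect_identical(out$volume, anat)
  expect_false(any(out$mask))

  cfg$lesion_prevalence[] <- 0
  cfg$lesion_prevalence[4, "PTE"] <- 1   # forced: every subject hit in ROI 4
  for (s in 1:5) {
    m <- plant_lesions(anat, parc, "PTE", cfg, s)$mask
    expect_gt(sum(m & parc$labels == 4), 0)
  }
})

test_that("prevalence gap raises across-subject variance in the target ROI", {
  cfg <- cohort_config(n_per_group = 2, grid_shape = c(24, 24, 10),
                       noise_sd = 0)
  parc <- generate_parcellation(cfg$grid_shape)
  anat <- generate_anatomy(cfg, 1L)
  cfg$lesion_prevalence[] <- 0
  cfg$lesion_prevalence[5, "PTE"] <- 0.5
  cfg$lesion_prevalence[5, "nonPTE"] <- 0.05
  roi_mean <- function(group, seed) {
    v <- plant_lesions(anat, parc, group, cfg, seed)$volume
    mean(v[parc$labels == 5])
  }
  pte <- vapply(1:60, function(s) roi_mean("PTE", s), 0)
  non <- vapply(1:60, function(s) roi_mean("nonPTE", 1000 + s), 0)
  sm <- permutation_f_test(matrix(pte, ncol = 1), matrix(non, ncol = 1),
                           nperm = 999, seed = 1)
  expect_lt(sm$p_raw, 0.01)
})

test_that("fMRI generator is seeded and hits its target correlations", {
  cfg <- cohort_config(n_per_group = 2, grid_shape = c(20, 20, 8),
                       effect = "null")
  parc <- generate_parcellation(cfg$grid_shape)
  t1 <- generate_fmri(parc, "PTE", cfg, 9L)
  t2 <- generate_fmri(parc, "PTE", cfg, 9L)
  expect_identical(t1, t2)
  expect_equal(dim(t1), c(cfg$grid_shape, cfg$n_volumes))

  # push one pair's target correlation to 1: ROI means nearly collinear
  base <- ptemarkers:::base_roi_correlation()
  shift <- matrix(0, 15, 15)
  shift[1, 2] <- shift[2, 1] <- 1 - base[1, 2]
  cfg2 <- cohort_config(n_per_group = 2, grid_shape = c(20, 20, 8),
                        connectivity_shift = shift, effect = "null",
                        ts_noise_sd = 0.2)
  cfg2$connectivity_shift <- shift
  ts <- generate_fmri(parc, "PTE", cfg2, 4L)
  rts <- roi_mean_timeseries(ts, parc)
  expect_gte(cor(rts[1, ], rts[2, ]), 0.9)
})

test_that("cohort generation is counted, labeled and bitwise reproducible", {
  cfg <- cohort_config(n_per_group = 2, grid_shape = c(20, 20, 8),
                       n_volumes = 24)
  co <- generate_cohort(cfg)
  expect_length(co$subjects, 4)
  expect_equal(sum(cohort_labels(co)$group == "PTE"), 2)
  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  expect_error(cohort_config(alff_band = c(0.01, 0.4)), "Nyquist")
  expect_error(cohort_config(repetition_interval = 2,
                             alff_band = c(0.1, 0.01)), "Nyquist")
  cfg <- cohort_config()
  cfg$lesion_prevalence[1, 1] <- 1.5
  expect_error(ptemarkers:::validate_cohort_config(cfg), "probabilities")
  cfg <- cohort_config()
  cfg$alff_variance_ratio[3] <- -1
  expect_error(ptemarkers:::validate_cohort_config(cfg), "positive")
})
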