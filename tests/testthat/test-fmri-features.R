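test_that("ROI mean series averages member voxels", {
  parc <- generate_parcellation(c(20, 20, 8))
  nvox <- prod(dim(parc$labels))
  # identical series everywhere
  s <- sin(seq_len(20))
  ts <- matrix(rep(s, each = nvox), nvox, 20)
  rts <- roi_mean_timeseries(ts, parc)
  expect_equal(unname(rts[3, ]), s)
  # hand mean on a 2-voxel ROI: (1,2,3) and (3,2,1) -> (2,2,2)
  labs <- array(0L, c(2, 2, 1)); labs[1, 1, 1] <- 1L; labs[2, 1, 1] <- 1L
  p2 <- structure(list(labels = labs,
                       roi_table = data.frame(id = 1L, name = "only"),
                       mask = labs > 0), class = "pte_parcellation")
  ts2 <- rbind(c(1, 2, 3), c(3, 2, 1), 0, 0)
  expect_equal(unname(roi_mean_timeseries(ts2, p2)[1, ]), c(2, 2, 2))
  # cancellation
  ts3 <- rbind(c(1, 2, 3), -c(1, 2, 3), 0, 0)
  expect_equal(unname(roi_mean_timeseries(ts3, p2)[1, ]), c(0, 0, 0))
  # empty ROI errors with its name
  p3 <- p2; p3$roi_table <- data.frame(id = 1:2, name = c("only", "ghost"))
  expect_error(roi_mean_timeseries(ts2, p3), "ghost")
})

test_that("ALFF matches the analytic power of sinusoids", {
  T <- 153; tr <- 2; t <- (0:(T - 1)) * tr
  A <- 1.3
  expect_equal(alff(A * sin(2 * pi * 0.05 * t), tr), A^2 / 2,
               tolerance = 0.05)
  expect_equal(alff(rep(4, T), tr), 0)   # constant demeans to zero
  # out-of-band sinusoid leaks < 2% of its total power into the band
  s <- sin(2 * pi * 0.2 * t)
  expect_lt(alff(s, tr), 0.02 * mean((s - mean(s))^2))
  expect_error(alff(s, tr, band = c(0.01, 0.3)), "Nyquist")
  # additivity for orthogonal in-band sinusoids
  s1 <- sin(2 * pi * 0.03 * t); s2 <- 0.5 * sin(2 * pi * 0.07 * t)
  expect_equal(alff(s1 + s2, tr), alff(s1, tr) + alff(s2, tr),
               tolerance = 0.05)
})

test_that("lobe ALFF is the within-ROI average of voxel ALFF", {
  tr <- 2; T <- 64
  t <- (0:(T - 1)) * tr
  labs <- array(0L, c(2, 2, 1)); labs[1, 1, 1] <- 1L; labs[2, 1, 1] <- 1L
  parc <- structure(list(labels = labs,
                         roi_table = data.frame(id = 1L, name = "only"),
                         mask = labs > 0), class = "pte_parcellation")
  v1 <- 1.5 * sin(2 * pi * 0.04 * t)
  v2 <- 0.7 * sin(2 * pi * 0.06 * t)
  ts <- rbind(v1, v2, 0, 0)
  la <- lobe_alff(ts, parc, tr)
  expect_equal(unname(la[1]), (alff(v1, tr) + alff(v2, tr)) / 2,
               tolerance = 1e-10)
  # all-constant series gives a zero vector
  expect_equal(unname(lobe_alff(matrix(1, 4, T), parc, tr)[1]), 0)
})

test_that("connectivity produces the fixed 105-feature Fisher-z vector", {
  set.seed(1)
  rts <- matrix(rnorm(15 * 50), 15, 50)
  rownames(rts) <- paste0("R", 1:15)
  cf <- connectivity(rts)
  expect_equal(dim(cf$matrix), c(15, 15))
  expect_equal(unname(diag(cf$matrix)), rep(1, 15))
  expect_length(cf$z_vector, 105)
  expect_equal(cf$matrix, t(cf$matrix))
  # row-major upper-triangle ordering: first feature is (1,2), second (1,3)
  expect_equal(names(cf$z_vector)[1:2], c("conn_R1_R2", "conn_R1_R3"))
  expect_equal(unname(cf$z_vector[1]), atanh(cf$matrix[1, 2]))
  # perfect correlation clips instead of overflowing
  rts2 <- rts; rts2[2, ] <- rts2[1, ]
  z <- connectivity(rts2)$z_vector
  expect_true(all(is.finite(z)))
  rts3 <- rts; rts3[2, ] <- -rts3[1, ]
  expect_equal(connectivity(rts3)$matrix[1, 2], -1)
  # constant row errors with the ROI name
  rts4 <- rts; rts4[5, ] <- 2
  expect_error(connectivity(rts4), "R5")
})

test_that("r = 0.5 maps to z = 0.549306 and z is antisymmetric", {
  expect_equal(atanh(0.5), 0.549306, tolerance = 5e-7)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(atanh(-r), -atanh(r))
})

test_that("connectivity is invariant to affine rescaling of a series", {
  set.seed(2)
  rts <- matrix(rnorm(15 * 40), 15, 40)
  r1 <- connectivity(rts)$matrix
  rts[4, ] <- 3.7 * rts[4, ] + 11
  r2 <- connectivity(rts)$matrix
  expect_equal(r1, r2, tolerance = 1e-12)
})
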