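# Group-difference inference. The central statistic is a one-sided variance
# ratio: traumatic lesions hit different places in different subjects, so a
# group difference in lesion burden (or ALFF) shows up as a difference in
# across-subject *variance* rather than in the mean; significance is
# assessed by label permutation and corrected with Benjamini-Hochberg.

#' Pointwise variance-ratio F statistic
#'
#' `F(v) = s2_A(v) / s2_B(v)` with unbiased (n-1) sample variances; group A
#' (PTE) is always the numerator, matching the one-sided alternative
#' var_PTE > var_nonPTE. Voxels with zero denominator variance get `Inf`.
#'
#' @param a,b subjects-x-voxels matrices for the two groups (same voxel
#'   columns).
#' @return numeric vector of F values, one per voxel.
#' @export
pointwise_variance_f <- function(a, b) {
  stopifnot(ncol(a) == ncol(b), nrow(a) >= 2, nrow(b) >= 2)
  va <- matrixStats_colVars(a)
  vb <- matrixStats_colVars(b)
  f <- va / vb
  f[vb == 0 & va > 0] <- Inf
  f[vb == 0 & va == 0] <- NaN
  f
}

# Column variances without the matrixStats dependency.
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  (colSums(x * x) - colSums(x)^2 / n) / (n - 1)
}

#' Permutation variance F-test
#'
#' One-sided test of var_A > var_B at each voxel. The observed F is
#' compared against `nperm` relabelings; the same permutation is applied
#' to every voxel within an iteration, preserving the spatial correlation
#' structure of the maps. `p = (1 + #\{F_perm >= F_obs\}) / (nperm + 1)`, so
#' p is never exactly zero. When the number of distinct labelings
#' `choose(nA + nB, nA)` is at most `nperm`, the test switches to exhaustive
#' enumeration and returns the exact `p = #\{F_all >= F_obs\} / n_labelings`
#' (the identity labeling is one of them). Permuted infinite F values count
#' as ties at infinite observed voxels.
#'
#' @inheritParams pointwise_variance_f
#' @param nperm number of label permutations (default 1000).
#' @param seed integer seed for the permutation draws.
#' @return a `pte_statmap`: list with `F`, `p_raw`, `nperm` (permutations
#'   actually used), `exhaustive`, and `seed`.
#' @export
permutation_f_test <- function(a, b, nperm = 1000, seed = 1L) {
  if (nperm < 1) stop("nperm must be >= 1")
  na <- nrow(a); nb <- nrow(b)
  x <- rbind(a, b)
  f_obs <- pointwise_variance_f(a, b)
  n_label <- choose(na + nb, na)
  exhaustive <- is.finite(n_label) && n_label <= nperm
  if (exhaustive) {
    sel <- utils::combn(na + nb, na)
    nperm_used <- n_label
  } else {
    set.seed(seed)
    sel <- vapply(seq_len(nperm), function(k) sample.int(na + nb, na),
                  integer(na))
    nperm_used <- nperm
  }
  # all permuted F statistics in two BLAS products: indicator matrix of
  # group-A membership times the data and its square
  K <- ncol(sel)
  M <- matrix(0, na + nb, K)
  M[cbind(as.vector(sel), rep(seq_len(K), each = na))] <- 1
  tot1 <- colSums(x); tot2 <- colSums(x * x)
  sa1 <- crossprod(M, x); sa2 <- crossprod(M, x * x)
  va <- (sa2 - sa1^2 / na) / (na - 1)
  sb1 <- rep(tot1, each = K) - sa1; sb2 <- rep(tot2, each = K) - sa2
  vb <- (sb2 - sb1^2 / nb) / (nb - 1)
  fp <- va / vb
  fp[vb <= 0 & va > 0] <- Inf
  # relative tolerance so the identity labeling always ties with itself
  # despite summation-order rounding
  ge <- fp >= rep(f_obs, each = K) * (1 - 1e-10)
  ge[is.na(ge)] <- FALSE
  count_ge <- colSums(ge)
  p <- if (exhaustive) count_ge / n_label else (1 + count_ge) / (nperm + 1)
  structure(list(F = f_obs, p_raw = p, nperm = nperm_used,
                 exhaustive = exhaustive, seed = seed),
            class = "pte_statmap")
}

#' @export
print.pte_statmap <- function(x, ...) {
  cat("Permutation variance F-test over", length(x$F), "voxels;",
      if (x$exhaustive) "exhaustive" else "sampled", "with",
      x$nperm, "labelings\n")
  cat("  min p:", format(min(x$p_raw, na.rm = TRUE)),
      " voxels with p <= 0.05:", sum(x$p_raw <= 0.05, na.rm = TRUE), "\n")
  invisible(x)
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up FDR control at level `q`: with ordered p-values `p_(1) <= ... <=
#' p_(m)`, reject all hypotheses with `p <= p_(k*)` where `k*` is the
#' largest k such that `p_(k) <= k q / m`.
#'
#' @param p numeric p-values in (0, 1\].
#' @param q target false discovery rate (default 0.05).
#' @return logical rejection flags, NA where `p` is NA.
#' @export
bh_fdr <- function(p, q = 0.05) {
  out <- rep(NA, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH") <= q
  out
}

#' One-sided Wilcoxon rank-sum test
#'
#' Tests the alternative that `x` is stochastically greater than `y` (for
#' lesion volumes: PTE larger). Exact enumeration when both samples are
#' small without ties, normal approximation with tie correction otherwise
#' (the behaviour of [stats::wilcox.test()]).
#'
#' @param x,y numeric samples.
#' @param alternative `"x_greater"` (default) or `"two_sided"`.
#' @return the p-value.
#' @export
ranksum_test <- function(x, y, alternative = c("x_greater", "two_sided")) {
  alternative <- match.arg(alternative)
  alt <- if (alternative == "x_greater") "greater" else "two.sided"
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt,
                       exact = (length(x) + length(y) <= 12) &&
                         !anyDuplicated(c(x, y)))$p.value
  )
}

#' Lobe-wise group test table
#'
#' Per ROI: a one-sided rank-sum test on lesion volumes (PTE greater) and a
#' one-sided permutation F-test on the across-subject variance of mean ALFF
#' (PTE greater), each corrected across ROIs with Benjamini-Hochberg,
#' separately per measure.
#'
#' @param lesion_volumes subjects x 15 matrix of per-ROI lesion volumes.
#' @param alff_means subjects x 15 matrix of per-ROI mean ALFF.
#' @param groups character vector of `"PTE"` / `"nonPTE"` per subject.
#' @param nperm permutations for the ALFF variance test.
#' @param seed integer seed.
#' @param q FDR level for the significance flags.
#' @return data.frame with one row per ROI: `roi`, `p_lesion`, `p_alff`,
#'   `sig_lesion`, `sig_alff`.
#' @export
region_tests <- function(lesion_volumes, alff_means, groups,
                         nperm = 1000, seed = 1L, q = 0.05) {
  stopifnot(ncol(lesion_volumes) == ncol(alff_means),
            nrow(lesion_volumes) == length(groups),
            nrow(alff_means) == length(groups))
  if (is.null(colnames(lesion_volumes)))
    stop("lesion_volumes must carry ROI column names")
  is_pte <- groups == "PTE"
  p_les <- vapply(seq_len(ncol(lesion_volumes)), function(k) {
    ranksum_test(lesion_volumes[is_pte, k], lesion_volumes[!is_pte, k])
  }, 0)
  sm <- permutation_f_test(alff_means[is_pte, , drop = FALSE],
                           alff_means[!is_pte, , drop = FALSE],
                           nperm = nperm, seed = seed)
  data.frame(
    roi = colnames(lesion_volumes),
    p_lesion = p_les,
    p_alff = sm$p_raw,
    sig_lesion = bh_fdr(p_les, q),
    sig_alff = bh_fdr(sm$p_raw, q),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Voxel-wise group variance analysis of a stack of maps
#'
#' Convenience wrapper: runs [permutation_f_test()] over the in-mask voxels
#' of per-subject 3-D maps and returns volumetric F / p / FDR-mask arrays.
#'
#' @param maps list of per-subject 3-D arrays (same grid).
#' @param groups `"PTE"` / `"nonPTE"` per subject.
#' @param mask logical array of voxels to test (e.g. the brain mask); FDR
#'   correction runs across in-mask voxels only.
#' @inheritParams region_tests
#' @return list with arrays `F`, `p_raw`, `sig` and the `pte_statmap`.
#' @export
voxelwise_group_analysis <- function(maps, groups, mask,
                                     nperm = 1000, seed = 1L, q = 0.05) {
  stopifnot(length(maps) == length(groups))
  flat <- vapply(maps, function(m) as.vector(m)[as.vector(mask)],
                 numeric(sum(mask)))
  x <- t(flat)  # subjects x voxels
  is_pte <- groups == "PTE"
  sm <- permutation_f_test(x[is_pte, , drop = FALSE],
                           x[!is_pte, , drop = FALSE],
                           nperm = nperm, seed = seed)
  g <- dim(mask)
  fvol <- array(NA_real_, g); fvol[mask] <- sm$F
  pvol <- array(NA_real_, g); pvol[mask] <- sm$p_raw
  svol <- array(FALSE, g); svol[mask] <- bh_fdr(sm$p_raw, q)
  list(F = fvol, p_raw = pvol, sig = svol, statmap = sm)
}
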