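# From reconstruction residuals to per-ROI lesion volumes.

#' Histogram-match a volume to a reference
#'
#' Monotone quantile mapping of the in-mask intensities onto the
#' reference's in-mask empirical distribution (the synthetic counterpart of
#' histogram-equalizing each scan to a lesion-free subject). Background
#' voxels are untouched.
#'
#' @param volume 3-D array to transform.
#' @param reference 3-D array providing the target distribution.
#' @param mask logical array of in-brain voxels; defaults to
#'   `volume != 0 | reference != 0`.
#' @return the matched volume.
#' @export
histogram_match <- function(volume, reference, mask = NULL) {
  if (is.null(mask)) mask <- volume != 0 | reference != 0
  v <- volume[mask]
  r <- reference[mask]
  stopifnot(length(v) > 0, length(r) > 0)
  out <- volume
  if (max(v) == min(v)) {
    message("histogram_match: constant input volume; filling with reference median")
    out[mask] <- stats::median(r)
    return(out)
  }
  q <- (rank(v, ties.method = "average") - 0.5) / length(v)
  rs <- sort(r)
  out[mask] <- rs[pmax(1, ceiling(q * length(rs)))]
  out
}

#' 2-D median filter
#'
#' Replaces each pixel by the median of its `size x size` neighborhood,
#' with reflect padding at the borders. A 7x7 filter removes the isolated
#' high-residual pixels that survive VAE reconstruction.
#'
#' @param img numeric matrix.
#' @param size odd window size (default 7).
#' @return filtered matrix of the same shape.
#' @export
median_filter <- function(img, size = 7) {
  if (size %% 2 == 0) stop("median filter size must be odd")
  if (size == 1) return(img)
  h <- (size - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  # reflect-padded index vectors (edge pixels mirrored without repetition
  # beyond bounds)
  refl <- function(i, n) { i <- abs(i - 1) + 1; i[i > n] <- 2 * n - i[i > n]; i }
  ri <- refl(seq(1 - h, nr + h), nr)
  ci <- refl(seq(1 - h, nc + h), nc)
  pad <- img[ri, ci, drop = FALSE]
  stack <- array(NA_real_, c(nr, nc, size * size))
  k <- 0
  for (dr in 0:(size - 1)) for (dc in 0:(size - 1)) {
    k <- k + 1
    stack[, , k] <- pad[dr + seq_len(nr), dc + seq_len(nc)]
  }
  dim(stack) <- c(nr * nc, size * size)
  out <- apply(stack, 1, stats::median)
  matrix(out, nr, nc)
}

#' VAE lesion-score map of a volume
#'
#' Each axial slice is resized to the model input, decoded from the latent
#' mean, and the absolute residual `|original - decoded|` mapped back to
#' the native grid and median-filtered per slice. Larger scores mean larger
#' deviation from the learned normal anatomy.
#'
#' @param model a trained `pte_vae`.
#' @param volume 3-D array in \[0, 1\].
#' @param median_size median filter window (odd; default 7).
#' @param signed_positive if `TRUE`, keep only positive residuals
#'   (hyperintense relative to the decoding) instead of absolute values.
#' @return a `pte_lesion_scores` list with the nonnegative `scores` array.
#' @export
lesion_score_map <- function(model, volume, median_size = 7,
                             signed_positive = FALSE) {
  stopifnot(inherits(model, "pte_vae"))
  g <- dim(volume)
  insz <- model$arch$input_size
  nz <- g[3]
  slices <- array(0, c(insz, nz))
  for (zi in seq_len(nz))
    slices[, , zi] <- resize_bilinear(volume[, , zi], insz)
  rec <- reconstruct_batch(model, slices)
  scores <- array(0, g)
  for (zi in seq_len(nz)) {
    err <- slices[, , zi] - rec[, , zi]
    err <- if (signed_positive) pmax(err, 0) else abs(err)
    native <- resize_bilinear(err, g[1:2])
    scores[, , zi] <- median_filter(native, median_size)
  }
  structure(list(scores = scores), class = "pte_lesion_scores")
}

#' Binarize lesion scores across subjects with a voxel-wise one-class SVM
#'
#' At each in-mask voxel, a one-class SVM (RBF kernel, bandwidth from the
#' median heuristic, contamination parameter `nu`) is fitted to the
#' across-subject score sample; subjects flagged as outliers *with a score
#' above the sample median* (abnormally large reconstruction error) are
#' marked as lesioned at that voxel. Voxels where all subjects score
#' identically flag no one.
#'
#' @param score_maps list of per-subject score arrays on a shared grid (or
#'   `pte_lesion_scores` objects).
#' @param mask logical array restricting the voxels examined.
#' @param nu one-class SVM contamination parameter in (0, 1), default 0.1.
#' @return list of logical lesion-mask arrays, one per subject.
#' @export
binarize_lesions <- function(score_maps, mask, nu = 0.1) {
  score_maps <- lapply(score_maps, function(m)
    if (inherits(m, "pte_lesion_scores")) m$scores else m)
  n <- length(score_maps)
  if (n < 8) stop("binarize_lesions needs at least 8 subjects")
  stopifnot(nu > 0, nu < 1)
  g <- dim(score_maps[[1]])
  vox <- which(mask)
  S <- vapply(score_maps, function(m) as.vector(m)[vox], numeric(length(vox)))
  flags <- matrix(FALSE, length(vox), n)
  for (v in seq_len(length(vox))) {
    s <- S[v, ]
    if (max(s) - min(s) < 1e-12) next
    dd <- stats::dist(s)
    h2 <- stats::median(dd)^2
    if (h2 <= 0) h2 <- stats::var(s)
    # fit on the sorted sample so the decision rule depends only on the
    # multiset of scores: binarization is then exactly equivariant under
    # subject permutation
    fit <- e1071::svm(x = matrix(sort(s), ncol = 1),
                      type = "one-classification",
                      kernel = "radial", nu = nu, gamma = 1 / (2 * h2),
                      scale = FALSE)
    dv <- attr(stats::predict(fit, matrix(s, ncol = 1),
                              decision.values = TRUE),
               "decision.values")[, 1]
    # outliers sit on or below the decision boundary. A far-out point can
    # self-support at the nu-cap and land numerically *on* the boundary
    # (f ~ 0), so flag anything within a small margin of it, relative to
    # the bulk of clear inliers.
    margin <- if (any(dv > 0)) 0.05 * stats::median(dv[dv > 0]) else 0
    out <- dv <= margin
    flags[v, ] <- out & s > stats::median(s)
  }
  lapply(seq_len(n), function(i) {
    m <- array(FALSE, g)
    m[vox] <- flags[, i]
    m
  })
}

#' Per-ROI lesion volumes
#'
#' Counts of lesion-mask voxels in each ROI, in the fixed ROI order.
#'
#' @param mask logical lesion mask array.
#' @param parcellation a `pte_parcellation` on the same grid.
#' @return named length-15 vector of voxel counts.
#' @export
roi_lesion_volumes <- function(mask, parcellation) {
  stopifnot(all(dim(mask) == dim(parcellation$labels)))
  n_roi <- nrow(parcellation$roi_table)
  counts <- tabulate(parcellation$labels[mask & parcellation$labels > 0],
                     nbins = n_roi)
  names(counts) <- parcellation$roi_table$name
  counts
}
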