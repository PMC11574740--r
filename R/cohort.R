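# Lobe-level parcellation with 15 regions, mirroring the USCLobes scheme.
usc_lobe_names <- c(
  "L Frontal", "R Frontal", "L Parietal", "R Parietal",
  "L Temporal", "R Temporal", "L Occipital", "R Occipital",
  "L Insula", "R Insula", "L Cingulate", "R Cingulate",
  "Brainstem", "Cerebellum", "Corpus Callosum"
)

# Fractional (x, y, z) seed coordinates used to tile the brain mask into
# lobes: x = left-right, y = posterior-anterior, z = inferior-superior.
# Rough anatomical placement only; the tiling is what matters downstream.
.lobe_seeds <- matrix(c(
  0.35, 0.72, 0.60,   0.65, 0.72, 0.60,   # frontal
  0.35, 0.38, 0.78,   0.65, 0.38, 0.78,   # parietal
  0.18, 0.52, 0.38,   0.82, 0.52, 0.38,   # temporal
  0.36, 0.15, 0.55,   0.64, 0.15, 0.55,   # occipital
  0.38, 0.58, 0.46,   0.62, 0.58, 0.46,   # insula
  0.44, 0.58, 0.70,   0.56, 0.58, 0.70,   # cingulate
  0.50, 0.48, 0.18,                        # brainstem
  0.50, 0.22, 0.25,                        # cerebellum
  0.50, 0.55, 0.58                         # corpus callosum
), ncol = 3, byrow = TRUE)

#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic cohort generator. The defaults are the
#' study conditions the rest of the package is exercised under: 36 subjects
#' per group, 153 resting-state volumes at a repetition interval of 2 s, the
#' 0.01-0.1 Hz ALFF band, and group differences planted as lesion
#' *prevalence* gaps and ALFF *variance* ratios (not mean shifts) so that
#' variance-based group tests are the appropriate inference.
#'
#' @param n_per_group subjects per group (PTE and non-PTE).
#' @param grid_shape integer triplet of voxel dimensions.
#' @param n_volumes number of time points in the resting-state series.
#' @param repetition_interval sampling interval of the series in seconds.
#' @param alff_band low/high frequency cutoffs in Hz; must lie below the
#'   Nyquist frequency `1 / (2 * repetition_interval)`.
#' @param lesion_prevalence 15 x 2 matrix of per-ROI lesion probabilities,
#'   columns `PTE` and `nonPTE`.
#' @param lesion_intensity additive hyperintensity of a planted lesion, in
#'   the \[0, 1\] intensity units of the anatomy.
#' @param lesion_radius lesion blob radius in voxels.
#' @param alff_variance_ratio length-15 vector: across-subject variance of
#'   ROI ALFF in the PTE group relative to the non-PTE group.
#' @param connectivity_shift symmetric 15 x 15 matrix added to the base ROI
#'   correlation matrix for PTE subjects (zero diagonal).
#' @param noise_sd anatomical voxel noise standard deviation.
#' @param ts_noise_sd white-noise standard deviation added to each voxel's
#'   time series on top of its ROI signal.
#' @param alff_amp_spread baseline across-subject spread of the ROI
#'   amplitude scale (the non-PTE coefficient of variation of band power).
#' @param effect convenience preset: `"default"` plants the standard
#'   effects, `"null"` removes every group difference (for calibration
#'   studies), `"strong"` widens all gaps (for power/recovery studies).
#' @param seed integer seed from which all per-subject seeds are derived.
#' @return an object of class `pte_cohort_config`.
#' @export
cohort_config <- function(n_per_group = 36,
                          grid_shape = c(64, 64, 16),
                          n_volumes = 153,
                          repetition_interval = 2.0,
                          alff_band = c(0.01, 0.1),
                          lesion_prevalence = NULL,
                          lesion_intensity = 0.15,
                          lesion_radius = 3,
                          alff_variance_ratio = NULL,
                          connectivity_shift = NULL,
                          noise_sd = 0.05,
                          ts_noise_sd = 1.0,
                          alff_amp_spread = 0.2,
                          effect = c("default", "null", "strong"),
                          seed = 1L) {
  effect <- match.arg(effect)
  nm <- usc_lobe_names

  if (is.null(lesion_prevalence)) {
    base <- switch(effect, default = 0.10, null = 0.10, strong = 0.05)
    pte <- rep(base, 15)
    names(pte) <- nm
    if (effect == "default") {
      pte[c("L Temporal", "R Temporal")] <- 0.45
      pte["Cerebellum"] <- 0.40
      pte["R Occipital"] <- 0.35
    } else if (effect == "strong") {
      pte[c("L Temporal", "R Temporal", "Cerebellum", "R Occipital")] <- 0.90
    }
    lesion_prevalence <- cbind(PTE = pte, nonPTE = rep(base, 15))
    rownames(lesion_prevalence) <- nm
  }
  if (is.null(alff_variance_ratio)) {
    alff_variance_ratio <- rep(1, 15)
    names(alff_variance_ratio) <- nm
    if (effect == "default") {
      alff_variance_ratio["R Temporal"] <- 4
      alff_variance_ratio["R Parietal"] <- 3
      alff_variance_ratio["L Occipital"] <- 3
      alff_variance_ratio["R Occipital"] <- 2
    } else if (effect == "strong") {
      alff_variance_ratio[c("L Temporal", "R Temporal", "R Parietal",
                            "L Occipital", "R Occipital",
                            "Cerebellum")] <- 8
    }
  }
  if (is.null(connectivity_shift)) {
    connectivity_shift <- matrix(0, 15, 15, dimnames = list(nm, nm))
    shift <- switch(effect, default = -0.15, null = 0, strong = -0.35)
    pairs <- rbind(c("L Temporal", "L Frontal"),
                   c("R Temporal", "R Frontal"),
                   c("L Temporal", "R Temporal"))
    if (effect == "strong") {
      # temporal decoupling from frontal, parietal, insular and cerebellar
      # regions: a strong effect in every one of the planted channels
      for (a in c("L Temporal", "R Temporal"))
        for (b in c("L Frontal", "R Frontal", "L Parietal", "R Parietal",
                    "L Insula", "R Insula", "Cerebellum"))
          pairs <- rbind(pairs, c(a, b))
    }
    for (k in seq_len(nrow(pairs))) {
      connectivity_shift[pairs[k, 1], pairs[k, 2]] <- shift
      connectivity_shift[pairs[k, 2], pairs[k, 1]] <- shift
    }
  }
  if (effect == "strong") lesion_intensity <- max(lesion_intensity, 0.3)

  cfg <- structure(list(
    n_per_group = as.integer(n_per_group),
    grid_shape = as.integer(grid_shape),
    n_volumes = as.integer(n_volumes),
    repetition_interval = repetition_interval,
    alff_band = alff_band,
    lesion_prevalence = lesion_prevalence,
    lesion_intensity = lesion_intensity,
    lesion_radius = lesion_radius,
    alff_variance_ratio = alff_variance_ratio,
    connectivity_shift = connectivity_shift,
    noise_sd = noise_sd,
    ts_noise_sd = ts_noise_sd,
    alff_amp_spread = alff_amp_spread,
    effect = effect,
    seed = as.integer(seed)
  ), class = "pte_cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_per_group >= 2,
            length(cfg$grid_shape) == 3, all(cfg$grid_shape >= 4),
            cfg$n_volumes >= 16,
            cfg$repetition_interval > 0)
  nyq <- 1 / (2 * cfg$repetition_interval)
  if (!(cfg$alff_band[1] < cfg$alff_band[2] && cfg$alff_band[2] < nyq))
    stop("alff_band must satisfy low < high < Nyquist (", signif(nyq, 3), " Hz)")
  if (any(cfg$lesion_prevalence < 0 | cfg$lesion_prevalence > 1))
    stop("lesion prevalences must be probabilities in [0, 1]")
  if (any(cfg$alff_variance_ratio <= 0))
    stop("alff_variance_ratio entries must be positive")
  if (!isTRUE(all.equal(cfg$connectivity_shift, t(cfg$connectivity_shift))))
    stop("connectivity_shift must be symmetric")
  invisible(cfg)
}

# Ellipsoidal brain mask on a grid; semi-axes proportional to the grid.
brain_mask <- function(grid_shape) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- 0.46 * nx; ay <- 0.46 * ny; az <- 0.44 * nz
  x <- ((seq_len(nx) - cx) / ax)^2
  y <- ((seq_len(ny) - cy) / ay)^2
  z <- ((seq_len(nz) - cz) / az)^2
  r2 <- outer(outer(x, y, `+`), z, `+`)
  r2 <= 1
}

#' Generate the 15-lobe synthetic parcellation
#'
#' Deterministically tiles an ellipsoidal brain mask into 15 contiguous
#' labeled regions named after the USCLobes lobes, by nearest-seed
#' (Voronoi) assignment of in-mask voxels to fixed anatomical seed points.
#' Voxels outside the brain mask carry label 0.
#'
#' @param grid_shape integer triplet of voxel dimensions.
#' @return a `pte_parcellation`: list with `labels` (integer array),
#'   `roi_table` (data.frame of `id`, `name`, ordered and fixed), and the
#'   logical `mask`.
#' @export
generate_parcellation <- function(grid_shape) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3)
  mask <- brain_mask(grid_shape)
  idx <- which(mask, arr.ind = TRUE)
  # normalised coordinates in (0,1)
  co <- sweep(idx - 0.5, 2, grid_shape, "/")
  seeds <- .lobe_seeds
  d2 <- matrix(0, nrow(co), 15)
  for (k in 1:15) {
    d2[, k] <- (co[, 1] - seeds[k, 1])^2 + (co[, 2] - seeds[k, 2])^2 +
      (co[, 3] - seeds[k, 3])^2
  }
  lab_in <- max.col(-d2, ties.method = "first")
  labels <- array(0L, grid_shape)
  labels[mask] <- lab_in
  counts <- tabulate(lab_in, nbins = 15)
  if (any(counts < 27)) {
    worst <- which.min(counts)
    stop("grid too small: ROI '", usc_lobe_names[worst], "' has only ",
         counts[worst], " voxels (< 27)")
  }
  structure(list(
    labels = labels,
    roi_table = data.frame(id = 1:15, name = usc_lobe_names,
                           stringsAsFactors = FALSE),
    mask = mask
  ), class = "pte_parcellation")
}

#' @export
print.pte_parcellation <- function(x, ...) {
  cat("Synthetic lobe parcellation:", paste(dim(x$labels), collapse = " x "),
      "grid,", sum(x$mask), "in-mask voxels, 15 ROIs\n")
  invisible(x)
}

#' Generate a FLAIR-like anatomical volume
#'
#' A smooth brain-masked intensity field (bright centre fading towards the
#' ellipsoid boundary with a fixed low-frequency texture) plus i.i.d.
#' Gaussian voxel noise of sd `noise_sd`, clipped to \[0, 1\]. Background
#' voxels are exactly zero.
#'
#' @param config a [cohort_config()].
#' @param subject_seed integer seed for the subject's noise draw.
#' @return numeric 3-D array in \[0, 1\].
#' @export
generate_anatomy <- function(config, subject_seed) {
  g <- config$grid_shape
  mask <- brain_mask(g)
  cx <- (g[1] + 1) / 2; cy <- (g[2] + 1) / 2; cz <- (g[3] + 1) / 2
  x <- ((seq_len(g[1]) - cx) / (0.46 * g[1]))^2
  y <- ((seq_len(g[2]) - cy) / (0.46 * g[2]))^2
  z <- ((seq_len(g[3]) - cz) / (0.44 * g[3]))^2
  r2 <- outer(outer(x, y, `+`), z, `+`)
  xs <- (seq_len(g[1]) - 0.5) / g[1]
  ys <- (seq_len(g[2]) - 0.5) / g[2]
  tex <- outer(0.04 * sin(2 * pi * 1.5 * xs), 0.04 * cos(2 * pi * 1.5 * ys), `+`)
  base <- 0.35 + 0.30 * (1 - pmin(r2, 1)) + as.vector(tex)
  vol <- array(base, g)
  if (config$noise_sd > 0) {
    set.seed(derive_seed(subject_seed, 101L))
    vol <- vol + array(stats::rnorm(prod(g), 0, config$noise_sd), g)
  }
  vol[!mask] <- 0
  vol[mask] <- clip01(vol[mask])
  vol
}

#' Plant group-dependent hyperintense lesions
#'
#' For each ROI, a lesion is planted with the group's prevalence
#' probability: one spherical hyperintense blob of radius `lesion_radius`
#' and additive contrast `lesion_intensity`, centred uniformly at an ROI
#' voxel. A higher prevalence in one group raises that group's
#' across-subject intensity variance in the ROI, which is exactly the
#' signal the downstream variance F-test is designed to detect.
#'
#' @param anat anatomy from [generate_anatomy()].
#' @param parcellation a [generate_parcellation()] result.
#' @param group `"PTE"` or `"nonPTE"`.
#' @param config a [cohort_config()].
#' @param subject_seed integer seed for the Bernoulli draws and centres.
#' @return list with `volume` (lesioned anatomy) and `mask` (logical array
#'   of true lesion voxels).
#' @export
plant_lesions <- function(anat, parcellation, group, config, subject_seed) {
  stopifnot(group %in% c("PTE", "nonPTE"))
  g <- dim(anat)
  prev <- config$lesion_prevalence[, group]
  if (length(prev) != nrow(parcellation$roi_table))
    stop("lesion prevalence must be defined for every ROI")
  set.seed(derive_seed(subject_seed, 202L))
  lesion_mask <- array(FALSE, g)
  labs <- parcellation$labels
  for (k in parcellation$roi_table$id) {
    if (stats::runif(1) >= prev[k]) next
    vox <- which(labs == k, arr.ind = TRUE)
    ctr <- vox[sample.int(nrow(vox), 1), ]
    r <- config$lesion_radius
    # shrink the blob if it would exceed the ROI's extent from this centre
    ext <- sqrt(max(rowSums(sweep(vox, 2, ctr)^2)))
    if (r > ext) {
      r <- max(1, floor(ext))
      warning("lesion radius shrunk to ", r, " to fit ROI '",
              parcellation$roi_table$name[k], "'")
    }
    xr <- max(1, ctr[1] - r):min(g[1], ctr[1] + r)
    yr <- max(1, ctr[2] - r):min(g[2], ctr[2] + r)
    zr <- max(1, ctr[3] - r):min(g[3], ctr[3] + r)
    sub <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
    inside <- rowSums(sweep(sub, 2, ctr)^2) <= r^2
    sub <- sub[inside, , drop = FALSE]
    keep <- parcellation$mask[sub]
    sub <- sub[keep, , drop = FALSE]
    lesion_mask[sub] <- TRUE
  }
  vol <- anat
  vol[lesion_mask] <- clip01(vol[lesion_mask] + config$lesion_intensity)
  list(volume = vol, mask = lesion_mask)
}

# Base inter-lobe correlation: moderate global coupling that decays with
# seed-point distance, repaired to a valid correlation matrix.
base_roi_correlation <- function() {
  d <- as.matrix(stats::dist(.lobe_seeds))
  m <- 0.25 + 0.45 * exp(-d / 0.35)
  diag(m) <- 1
  repair_correlation(m)
}

#' Generate a band-limited ROI-driven resting-state series
#'
#' Draws 15 latent ROI signals from a multivariate normal whose correlation
#' matrix is the base lobe-coupling matrix, perturbed for PTE subjects by
#' `connectivity_shift` and projected back to the nearest positive-definite
#' correlation matrix (eigenvalue clipping). The latents are band-pass
#' filtered to `alff_band` and scaled by a per-subject, per-ROI amplitude
#' factor whose across-subject variance differs between groups by
#' `alff_variance_ratio`. Each in-mask voxel's series is its ROI latent
#' plus white noise; background voxels are zero.
#'
#' @inheritParams plant_lesions
#' @return numeric 4-D array `grid_shape x n_volumes`.
#' @export
generate_fmri <- function(parcellation, group, config, subject_seed) {
  stopifnot(group %in% c("PTE", "nonPTE"))
  T <- config$n_volumes
  C <- base_roi_correlation()
  if (group == "PTE") C <- C + config$connectivity_shift
  C <- repair_correlation(C)
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    stop("perturbed correlation matrix not positive definite (min eigenvalue ",
         signif(ev, 3), ")")
  set.seed(derive_seed(subject_seed, 303L))
  Z <- matrix(stats::rnorm(T * 15), T, 15) %*% chol(C)
  Z <- bandpass_columns(Z, config$repetition_interval, config$alff_band)
  # unit-variance latents, then per-subject ROI band-power scale m_k with
  # var_PTE(m) / var_nonPTE(m) = alff_variance_ratio
  Z <- scale(Z, center = TRUE, scale = apply(Z, 2, stats::sd))
  tau <- config$alff_amp_spread *
    if (group == "PTE") sqrt(config$alff_variance_ratio) else rep(1, 15)
  m <- pmax(0.1, stats::rnorm(15, mean = 1, sd = tau))
  Z <- sweep(Z, 2, sqrt(m), "*")
  g <- config$grid_shape
  lab_flat <- as.vector(parcellation$labels)
  ts <- matrix(0, prod(g), T)
  inm <- lab_flat > 0
  ts[inm, ] <- t(Z)[lab_flat[inm], , drop = FALSE] +
    matrix(stats::rnorm(sum(inm) * T, 0, config$ts_noise_sd), sum(inm), T)
  array(ts, c(g, T))
}

# Keep only Fourier components with band_low <= f <= band_high (both
# signs), zeroing DC and out-of-band bins; columns filtered independently.
bandpass_columns <- function(x, tr, band) {
  T <- nrow(x)
  f <- (seq_len(T) - 1) / (T * tr)
  f <- pmin(f, 1 / tr - f)  # fold to [0, Nyquist]
  keep <- f >= band[1] & f <= band[2]
  X <- stats::mvfft(x)
  X[!keep, ] <- 0
  Re(stats::mvfft(X, inverse = TRUE)) / T
}

#' Generate a full synthetic cohort
#'
#' `n_per_group` PTE and `n_per_group` non-PTE subjects, each with a
#' lesioned FLAIR-like anatomy, a ground-truth lesion mask, and a
#' resting-state series, all on a shared grid with a shared parcellation.
#' Per-subject seeds are derived deterministically from `config$seed`, so
#' identical configurations reproduce the cohort bitwise and any single
#' subject can be regenerated in isolation.
#'
#' @param config a [cohort_config()].
#' @param with_fmri set `FALSE` to skip time-series generation when only
#'   anatomy is needed (faster).
#' @return a `pte_cohort`: list with `subjects` (each a list of
#'   `subject_id`, `group`, `anat`, `ts`, `true_lesion_mask`, `seed`),
#'   `parcellation`, and `config`.
#' @export
generate_cohort <- function(config, with_fmri = TRUE) {
  validate_cohort_config(config)
  parc <- generate_parcellation(config$grid_shape)
  n <- config$n_per_group
  subjects <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    group <- if (i <= n) "PTE" else "nonPTE"
    s_seed <- derive_seed(config$seed, i)
    anat <- generate_anatomy(config, s_seed)
    les <- plant_lesions(anat, parc, group, config, s_seed)
    subjects[[i]] <- list(
      subject_id = sprintf("sub-%03d", i),
      group = group,
      anat = les$volume,
      true_lesion_mask = les$mask,
      ts = if (with_fmri) generate_fmri(parc, group, config, s_seed) else NULL,
      seed = s_seed
    )
  }
  structure(list(subjects = subjects, parcellation = parc, config = config),
            class = "pte_cohort")
}

#' @export
print.pte_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, `[[`, "", "group")
  cat("Synthetic TBI cohort:", sum(groups == "PTE"), "PTE +",
      sum(groups == "nonPTE"), "non-PTE subjects on a",
      paste(x$config$grid_shape, collapse = " x "), "grid\n")
  cat("Resting-state series:", x$config$n_volumes, "volumes @",
      x$config$repetition_interval, "s; effects preset:", x$config$effect, "\n")
  invisible(x)
}

#' Labels of a cohort as a data frame
#' @param cohort a `pte_cohort`.
#' @return data.frame with `subject_id` and `group`.
#' @export
cohort_labels <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    group = vapply(cohort$subjects, `[[`, "", "group"),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort to disk
#'
#' Per-subject NIfTI volumes (`<id>_anat.nii.gz`, `<id>_bold.nii.gz`,
#' `<id>_lesionmask.nii.gz`), the parcellation NIfTI, a ROI names TSV
#' (columns `id`, `name`) and a labels CSV (`subject_id`, `group`).
#'
#' @param cohort a `pte_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(cohort$parcellation$labels, file.path(dir, "parcellation.nii.gz"))
  utils::write.table(cohort$parcellation$roi_table,
                     file.path(dir, "roi_names.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort_labels(cohort), file.path(dir, "labels.csv"),
                   row.names = FALSE)
  for (s in cohort$subjects) {
    write_volume(s$anat, file.path(dir, paste0(s$subject_id, "_anat.nii.gz")))
    write_volume(s$true_lesion_mask * 1L,
                 file.path(dir, paste0(s$subject_id, "_lesionmask.nii.gz")))
    if (!is.null(s$ts))
      write_volume(s$ts, file.path(dir, paste0(s$subject_id, "_bold.nii.gz")),
                   tr = cohort$config$repetition_interval)
  }
  invisible(dir)
}
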