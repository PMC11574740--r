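# ALFF and ROI-connectivity features from 4-D resting-state series.

#' Per-ROI mean time series
#'
#' Averages the series over each ROI's member voxels, in the fixed ROI
#' order of the parcellation table.
#'
#' @param ts 4-D array (grid x time) or voxels-x-time matrix matching the
#'   parcellation grid.
#' @param parcellation a `pte_parcellation`.
#' @return 15 x T matrix, rows named by ROI.
#' @export
roi_mean_timeseries <- function(ts, parcellation) {
  if (length(dim(ts)) == 4) ts <- flatten_ts(ts)
  labs <- as.vector(parcellation$labels)
  if (nrow(ts) != length(labs))
    stop("time series voxel count does not match the parcellation grid")
  counts <- tabulate(labs, nbins = nrow(parcellation$roi_table))
  empty <- which(counts == 0)
  if (length(empty))
    stop("empty ROI: '", parcellation$roi_table$name[empty[1]], "'")
  inm <- labs > 0
  sums <- rowsum(ts[inm, , drop = FALSE], group = labs[inm], reorder = TRUE)
  out <- sums / counts
  rownames(out) <- parcellation$roi_table$name
  out
}

#' ALFF of a single series
#'
#' Amplitude of low-frequency fluctuations, computed as the signal power in
#' `band` (default 0.01-0.1 Hz): the series is demeaned, its periodogram
#' taken by discrete Fourier transform, and the power in bins with
#' `band[1] <= f <= band[2]` summed. The normalization follows Parseval's
#' convention, so the power summed over all bins equals the series'
#' (population) variance, and a sinusoid of amplitude A inside the band
#' contributes approximately A^2/2.
#'
#' @param series numeric vector, length >= 16.
#' @param repetition_interval sampling interval in seconds.
#' @param band frequency band (low, high) in Hz, inside (0, Nyquist\].
#' @return nonnegative scalar band power in signal-squared units.
#' @export
alff <- function(series, repetition_interval, band = c(0.01, 0.1)) {
  T <- length(series)
  stopifnot(T >= 16)
  nyq <- 1 / (2 * repetition_interval)
  if (!(band[1] >= 0 && band[1] < band[2] && band[2] <= nyq))
    stop("band must lie inside (0, Nyquist = ", signif(nyq, 3), " Hz)")
  x <- series - mean(series)
  p <- Mod(stats::fft(x))^2 / T^2
  kmax <- floor(T / 2)
  f <- (1:kmax) / (T * repetition_interval)
  # one-sided spectrum: double every bin except an exact Nyquist bin
  w <- rep(2, kmax)
  if (T %% 2 == 0) w[kmax] <- 1
  sel <- f >= band[1] & f <= band[2]
  sum(w[sel] * p[1 + (1:kmax)[sel]])
}

# Vectorised per-voxel ALFF of a voxels x T matrix.
alff_matrix <- function(mat, repetition_interval, band) {
  T <- ncol(mat)
  nyq <- 1 / (2 * repetition_interval)
  if (!(band[1] >= 0 && band[1] < band[2] && band[2] <= nyq))
    stop("band must lie inside (0, Nyquist = ", signif(nyq, 3), " Hz)")
  x <- mat - rowMeans(mat)
  P <- Mod(stats::mvfft(t(x)))^2 / T^2
  kmax <- floor(T / 2)
  f <- (1:kmax) / (T * repetition_interval)
  w <- rep(2, kmax)
  if (T %% 2 == 0) w[kmax] <- 1
  sel <- which(f >= band[1] & f <= band[2])
  as.vector(crossprod(P[1 + sel, , drop = FALSE], w[sel]))
}

#' Per-ROI average ALFF
#'
#' Voxel-wise ALFF averaged within each ROI, in the fixed ROI order.
#'
#' @inheritParams roi_mean_timeseries
#' @param repetition_interval sampling interval in seconds.
#' @param band frequency band in Hz.
#' @return named length-15 vector of mean ALFF per ROI.
#' @export
lobe_alff <- function(ts, parcellation, repetition_interval,
                      band = c(0.01, 0.1)) {
  if (length(dim(ts)) == 4) ts <- flatten_ts(ts)
  labs <- as.vector(parcellation$labels)
  if (nrow(ts) != length(labs))
    stop("time series voxel count does not match the parcellation grid")
  counts <- tabulate(labs, nbins = nrow(parcellation$roi_table))
  empty <- which(counts == 0)
  if (length(empty))
    stop("empty ROI: '", parcellation$roi_table$name[empty[1]], "'")
  inm <- labs > 0
  a <- alff_matrix(ts[inm, , drop = FALSE], repetition_interval, band)
  out <- as.vector(rowsum(a, group = labs[inm], reorder = TRUE)) / counts
  names(out) <- parcellation$roi_table$name
  out
}

#' Voxel-wise ALFF map
#'
#' @inheritParams lobe_alff
#' @return 3-D array of ALFF values (zero outside the brain mask).
#' @export
alff_map <- function(ts, parcellation, repetition_interval,
                     band = c(0.01, 0.1)) {
  g <- dim(parcellation$labels)
  if (length(dim(ts)) == 4) ts <- flatten_ts(ts)
  labs <- as.vector(parcellation$labels)
  stopifnot(nrow(ts) == length(labs))
  out <- numeric(length(labs))
  inm <- labs > 0
  out[inm] <- alff_matrix(ts[inm, , drop = FALSE], repetition_interval, band)
  array(out, g)
}

#' ROI-to-ROI functional connectivity features
#'
#' The 15 x 15 Pearson correlation matrix of the ROI-mean series, plus its
#' strict upper triangle in fixed row-major order (1,2), (1,3), ...,
#' (14,15) after the Fisher z transform (atanh). Perfect correlations are
#' clipped to `1 - 1e-7` in magnitude so every feature stays finite.
#'
#' @param roi_ts 15 x T matrix of ROI-mean series (rows named by ROI).
#' @return list with `matrix` (15 x 15 correlations) and `z_vector`
#'   (named length-105 Fisher-z features).
#' @export
connectivity <- function(roi_ts) {
  n <- nrow(roi_ts)
  stopifnot(ncol(roi_ts) >= 3)
  sds <- apply(roi_ts, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(roi_ts)[which(sds == 0)[1]] %||% which(sds == 0)[1]
    stop("constant ROI series: '", bad, "'")
  }
  r <- stats::cor(t(roi_ts))
  pairs <- upper_pairs(n)
  rv <- r[pairs]
  z <- atanh(pmin(pmax(rv, -1 + 1e-7), 1 - 1e-7))
  nm <- rownames(roi_ts) %||% as.character(seq_len(n))
  names(z) <- paste0("conn_", gsub(" ", ".", nm[pairs[, 1]]),
                     "_", gsub(" ", ".", nm[pairs[, 2]]))
  list(matrix = r, z_vector = z)
}
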