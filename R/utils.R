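# Deterministic per-subject seed derived from a global seed and subject index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 69621) %% 2147483563) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(1, pmax(0, x))

#' Area under the ROC curve from scores and binary labels
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' positive receives a higher score than a randomly chosen negative, with
#' ties counted as one half.
#'
#' @param scores numeric vector of decision scores (larger = more positive).
#' @param labels logical or 0/1 vector, `TRUE`/1 marking the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  r <- rank(scores)
  n1 <- as.numeric(sum(labels))
  n0 <- as.numeric(sum(!labels))
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Project a symmetric matrix to the nearest (in a simple spectral sense)
# positive-definite correlation matrix: clip eigenvalues at `eps`, rebuild,
# then renormalise the diagonal to one.
repair_correlation <- function(m, eps = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) < eps) {
    v <- pmax(e$values, eps)
    m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / outer(d, d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
  }
  m
}

# Bilinear resize of a 2-D matrix to `out_dim = c(rows, cols)`.
# Used to map native slices onto the network input grid and back.
resize_bilinear <- function(img, out_dim) {
  nr <- nrow(img); nc <- ncol(img)
  or <- out_dim[1]; oc <- out_dim[2]
  if (nr == or && nc == oc) return(img)
  # map output pixel centres into input coordinates
  rx <- (seq_len(or) - 0.5) * nr / or + 0.5
  cx <- (seq_len(oc) - 0.5) * nc / oc + 0.5
  r0 <- pmin(pmax(floor(rx), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(cx), 1), nc); c1 <- pmin(c0 + 1, nc)
  fr <- pmin(pmax(rx - r0, 0), 1)
  fc <- pmin(pmax(cx - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE] * (1 - fr) + img[r1, c0, drop = FALSE] * fr
  b <- img[r0, c1, drop = FALSE] * (1 - fr) + img[r1, c1, drop = FALSE] * fr
  a * rep(1 - fc, each = or) + b * rep(fc, each = or)
}

# Row-major strict upper-triangle index pairs of an n x n matrix:
# (1,2),(1,3),...,(1,n),(2,3),...,(n-1,n).
upper_pairs <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  cbind(i = i, j = j)
}

# Column-stacked voxel view of a 4-D array: voxels x T.
flatten_ts <- function(ts) {
  d <- dim(ts)
  stopifnot(length(d) == 4)
  dim(ts) <- c(prod(d[1:3]), d[4])
  ts
}
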