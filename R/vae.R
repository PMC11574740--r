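# Slice-wise variational autoencoder for unsupervised lesion scoring.
# Trained on (mostly lesion-free) FLAIR-like slices, the VAE learns to
# encode normal anatomy; applied to a lesioned slice it decodes a
# lesion-free version, so the reconstruction residual localizes lesions.

#' VAE architecture specification
#'
#' Encoder: three conv blocks (3x3 conv, stride 2, batch-norm, ReLU) with
#' the given channel widths; bottleneck: two fully connected heads for the
#' latent mean and log-variance; decoder: one fully connected layer, three
#' deconv blocks (4x4 transposed conv, stride 2, batch-norm, ReLU), and a
#' final same-size deconvolution to one channel with a sigmoid output.
#'
#' @param input_size pixel dimensions of a slice, each divisible by 8.
#' @param channels encoder channel widths (length 3).
#' @param latent_dim latent dimension (>= 1).
#' @return a `pte_vae_arch` list.
#' @export
vae_architecture <- function(input_size = c(128, 128),
                             channels = c(32, 64, 128),
                             latent_dim = 32) {
  stopifnot(length(input_size) == 2, all(input_size %% 8 == 0),
            length(channels) == 3, latent_dim >= 1)
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 latent_dim = as.integer(latent_dim)),
            class = "pte_vae_arch")
}

#' VAE training configuration
#' @param epochs training epochs.
#' @param batch_size slices per batch.
#' @param learning_rate Adam step size.
#' @param kl_weight weight of the KL term in the evidence bound; 0 reduces
#'   the objective to a plain autoencoder.
#' @param seed seed for initialization, shuffling and the reparametrization
#'   noise.
#' @return a list of training settings.
#' @export
vae_train_config <- function(epochs = 20, batch_size = 16,
                             learning_rate = 1e-3, kl_weight = 1.0,
                             seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, kl_weight >= 0)
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       learning_rate = learning_rate, kl_weight = kl_weight,
       seed = as.integer(seed))
}

vae_geoms <- function(arch) {
  H <- arch$input_size[1]; W <- arch$input_size[2]
  ch <- arch$channels
  list(
    e1 = conv_geom(H, W, 1L, k = 3, stride = 2, pad = 1),
    e2 = conv_geom(H / 2, W / 2, ch[1], k = 3, stride = 2, pad = 1),
    e3 = conv_geom(H / 4, W / 4, ch[2], k = 3, stride = 2, pad = 1),
    # transposed convolutions share conv geometry, traversed backwards
    d1 = conv_geom(H / 4, W / 4, ch[2], k = 4, stride = 2, pad = 1),
    d2 = conv_geom(H / 2, W / 2, ch[1], k = 4, stride = 2, pad = 1),
    d3 = conv_geom(H, W, ch[1], k = 4, stride = 2, pad = 1),
    fin = conv_geom(H, W, ch[1], k = 3, stride = 1, pad = 1)
  )
}

vae_init <- function(arch, seed) {
  set.seed(seed)
  ch <- arch$channels; L <- arch$latent_dim
  H8 <- arch$input_size[1] / 8; W8 <- arch$input_size[2] / 8
  D <- H8 * W8 * ch[3]
  params <- list(
    cW1 = he_init(9 * 1, ch[1], 9), cb1 = rep(0, ch[1]),
    g1 = rep(1, ch[1]), be1 = rep(0, ch[1]),
    cW2 = he_init(9 * ch[1], ch[2], 9 * ch[1]), cb2 = rep(0, ch[2]),
    g2 = rep(1, ch[2]), be2 = rep(0, ch[2]),
    cW3 = he_init(9 * ch[2], ch[3], 9 * ch[2]), cb3 = rep(0, ch[3]),
    g3 = rep(1, ch[3]), be3 = rep(0, ch[3]),
    Wmu = he_init(D, L, D), bmu = rep(0, L),
    Wlv = he_init(D, L, D), blv = rep(0, L),
    Wd = he_init(L, D, L), bd = rep(0, D),
    # deconv weights have dim (k*k*bigC) x smallC
    dW1 = he_init(16 * ch[2], ch[3], 16 * ch[3]), db1 = rep(0, ch[2]),
    dg1 = rep(1, ch[2]), dbe1 = rep(0, ch[2]),
    dW2 = he_init(16 * ch[1], ch[2], 16 * ch[2]), db2 = rep(0, ch[1]),
    dg2 = rep(1, ch[1]), dbe2 = rep(0, ch[1]),
    dW3 = he_init(16 * ch[1], ch[1], 16 * ch[1]), db3 = rep(0, ch[1]),
    dg3 = rep(1, ch[1]), dbe3 = rep(0, ch[1]),
    fW = he_init(9 * ch[1], 1, 9 * ch[1]), fb = 0
  )
  bn <- list(e1 = bn_new(ch[1]), e2 = bn_new(ch[2]), e3 = bn_new(ch[3]),
             d1 = bn_new(ch[2]), d2 = bn_new(ch[1]), d3 = bn_new(ch[1]))
  list(params = params, bn = bn)
}

# One full forward pass. `eps` NULL decodes from the latent mean
# (deterministic inference); otherwise z = mu + exp(lv/2) * eps.
vae_forward <- function(params, bn, geoms, arch, x, training, eps = NULL) {
  N <- dim(x)[4]
  ch <- arch$channels
  H8 <- arch$input_size[1] / 8; W8 <- arch$input_size[2] / 8
  D <- H8 * W8 * ch[3]

  bn_use <- function(nm, v, pg, pb) {
    b <- bn[[nm]]; b$gamma <- params[[pg]]; b$beta <- params[[pb]]
    r <- bn_forward(b, v, training = training)
    bn[[nm]] <<- r$bn
    r
  }
  c1 <- conv_forward(geoms$e1, x, params$cW1, params$cb1)
  b1 <- bn_use("e1", c1$y, "g1", "be1"); a1 <- relu(b1$y)
  c2 <- conv_forward(geoms$e2, a1, params$cW2, params$cb2)
  b2 <- bn_use("e2", c2$y, "g2", "be2"); a2 <- relu(b2$y)
  c3 <- conv_forward(geoms$e3, a2, params$cW3, params$cb3)
  b3 <- bn_use("e3", c3$y, "g3", "be3"); a3 <- relu(b3$y)
  Fm <- t(matrix(a3, D, N))
  mu <- sweep(Fm %*% params$Wmu, 2, params$bmu, `+`)
  lv <- sweep(Fm %*% params$Wlv, 2, params$blv, `+`)
  z <- if (is.null(eps)) mu else mu + exp(0.5 * lv) * eps
  d0 <- sweep(z %*% params$Wd, 2, params$bd, `+`)
  d0r <- relu(d0)
  h0 <- array(t(d0r), c(H8, W8, ch[3], N))
  u1 <- deconv_forward(geoms$d1, h0, params$dW1, params$db1)
  v1 <- bn_use("d1", u1$y, "dg1", "dbe1"); w1 <- relu(v1$y)
  u2 <- deconv_forward(geoms$d2, w1, params$dW2, params$db2)
  v2 <- bn_use("d2", u2$y, "dg2", "dbe2"); w2 <- relu(v2$y)
  u3 <- deconv_forward(geoms$d3, w2, params$dW3, params$db3)
  v3 <- bn_use("d3", u3$y, "dg3", "dbe3"); w3 <- relu(v3$y)
  fo <- conv_forward(geoms$fin, w3, params$fW, params$fb)
  y <- sigmoid(fo$y)
  list(y = y, bn = bn,
       cache = list(x = x, c1 = c1, b1 = b1, a1 = a1, c2 = c2, b2 = b2,
                    a2 = a2, c3 = c3, b3 = b3, a3 = a3, Fm = Fm, mu = mu,
                    lv = lv, z = z, eps = eps, d0 = d0, d0r = d0r, h0 = h0,
                    u1 = u1, v1 = v1, w1 = w1, u2 = u2, v2 = v2, w2 = w2,
                    u3 = u3, v3 = v3, w3 = w3, fo = fo, y = y, N = N, D = D))
}

vae_backward <- function(params, geoms, arch, cache, kl_weight) {
  N <- cache$N; D <- cache$D
  ch <- arch$channels
  H8 <- arch$input_size[1] / 8; W8 <- arch$input_size[2] / 8
  npix <- prod(arch$input_size)
  g <- list()

  dy <- 2 * (cache$y - cache$x) / (npix * N)
  dpre <- dy * cache$y * (1 - cache$y)
  bf <- conv_backward(geoms$fin, cache$fo$m, params$fW, dpre)
  g$fW <- bf$dW; g$fb <- bf$db
  dv3 <- relu_backward(cache$v3$y, bf$dx)
  bb3 <- bn_backward(cache$v3, dv3)
  g$dg3 <- bb3$dgamma; g$dbe3 <- bb3$dbeta
  bd3 <- deconv_backward(geoms$d3, cache$u3$xm, params$dW3, bb3$dx)
  g$dW3 <- bd3$dW; g$db3 <- bd3$db
  dv2 <- relu_backward(cache$v2$y, bd3$dx)
  bb2 <- bn_backward(cache$v2, dv2)
  g$dg2 <- bb2$dgamma; g$dbe2 <- bb2$dbeta
  bd2 <- deconv_backward(geoms$d2, cache$u2$xm, params$dW2, bb2$dx)
  g$dW2 <- bd2$dW; g$db2 <- bd2$db
  dv1 <- relu_backward(cache$v1$y, bd2$dx)
  bb1 <- bn_backward(cache$v1, dv1)
  g$dg1 <- bb1$dgamma; g$dbe1 <- bb1$dbeta
  bd1 <- deconv_backward(geoms$d1, cache$u1$xm, params$dW1, bb1$dx)
  g$dW1 <- bd1$dW; g$db1 <- bd1$db

  dd0r <- t(matrix(bd1$dx, D, N))
  dd0 <- dd0r; dd0[cache$d0 <= 0] <- 0
  g$Wd <- crossprod(cache$z, dd0); g$bd <- colSums(dd0)
  dz <- tcrossprod(dd0, params$Wd)
  kl_scale <- kl_weight / (npix * N)
  dmu <- dz + kl_scale * cache$mu
  dlv <- 0.5 * kl_scale * (exp(cache$lv) - 1)
  if (!is.null(cache$eps)) dlv <- dlv + dz * cache$eps * 0.5 * exp(0.5 * cache$lv)
  g$Wmu <- crossprod(cache$Fm, dmu); g$bmu <- colSums(dmu)
  g$Wlv <- crossprod(cache$Fm, dlv); g$blv <- colSums(dlv)
  dFm <- tcrossprod(dmu, params$Wmu) + tcrossprod(dlv, params$Wlv)

  da3 <- array(t(dFm), c(H8, W8, ch[3], N))
  db3_ <- relu_backward(cache$b3$y, da3)
  bbe3 <- bn_backward(cache$b3, db3_)
  g$g3 <- bbe3$dgamma; g$be3 <- bbe3$dbeta
  bc3 <- conv_backward(geoms$e3, cache$c3$m, params$cW3, bbe3$dx)
  g$cW3 <- bc3$dW; g$cb3 <- bc3$db
  db2_ <- relu_backward(cache$b2$y, bc3$dx)
  bbe2 <- bn_backward(cache$b2, db2_)
  g$g2 <- bbe2$dgamma; g$be2 <- bbe2$dbeta
  bc2 <- conv_backward(geoms$e2, cache$c2$m, params$cW2, bbe2$dx)
  g$cW2 <- bc2$dW; g$cb2 <- bc2$db
  db1_ <- relu_backward(cache$b1$y, bc2$dx)
  bbe1 <- bn_backward(cache$b1, db1_)
  g$g1 <- bbe1$dgamma; g$be1 <- bbe1$dbeta
  bc1 <- conv_backward(geoms$e1, cache$c1$m, params$cW1, bbe1$dx)
  g$cW1 <- bc1$dW; g$cb1 <- bc1$db
  g
}

vae_loss <- function(y, x, mu, lv, kl_weight, npix) {
  N <- dim(x)[4]
  recon <- sum((y - x)^2) / (npix * N)
  kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv)) / (npix * N)
  list(loss = recon + kl_weight * kl, recon = recon, kl = kl)
}

#' Train the lesion-scoring VAE
#'
#' Minimizes the Gaussian-reconstruction + KL evidence bound with Adam.
#' Training is deterministic given `train_config$seed` (initialization,
#' shuffling and reparametrization noise all derive from it).
#'
#' @param slices 3-D array (H x W x n_slices) of training slices matching
#'   `architecture$input_size`, values in \[0, 1\].
#' @param architecture a [vae_architecture()].
#' @param train_config a [vae_train_config()].
#' @return a `pte_vae` model with the learned weights, batch-norm running
#'   statistics, and the per-epoch training-loss curve.
#' @export
train_vae <- function(slices, architecture, train_config = vae_train_config()) {
  stopifnot(inherits(architecture, "pte_vae_arch"))
  d <- dim(slices)
  stopifnot(length(d) == 3,
            all(d[1:2] == architecture$input_size),
            d[3] >= 1)
  n <- d[3]
  bs <- min(train_config$batch_size, n)
  geoms <- vae_geoms(architecture)
  init <- vae_init(architecture, train_config$seed)
  params <- init$params; bn <- init$bn
  opt <- adam_new(params)
  npix <- prod(architecture$input_size)
  curve <- numeric(train_config$epochs)
  set.seed(derive_seed(train_config$seed, 7L))
  for (ep in seq_len(train_config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1, n, by = bs)) {
      sel <- ord[start:min(start + bs - 1, n)]
      if (length(sel) < 2) next  # batch-norm needs >= 2 samples
      x <- array(slices[, , sel], c(d[1], d[2], 1, length(sel)))
      eps <- matrix(stats::rnorm(length(sel) * architecture$latent_dim),
                    length(sel), architecture$latent_dim)
      fw <- vae_forward(params, bn, geoms, architecture, x,
                        training = TRUE, eps = eps)
      bn <- fw$bn
      l <- vae_loss(fw$y, x, fw$cache$mu, fw$cache$lv,
                    train_config$kl_weight, npix)
      if (!is.finite(l$loss))
        stop("non-finite loss at epoch ", ep, ", batch starting at ", start)
      grads <- vae_backward(params, geoms, architecture, fw$cache,
                            train_config$kl_weight)
      st <- adam_step(opt, params, grads, train_config$learning_rate)
      opt <- st$state; params <- st$params
      losses <- c(losses, l$loss)
    }
    curve[ep] <- mean(losses)
  }
  structure(list(arch = architecture, params = params, bn = bn,
                 curve = curve, final_loss = curve[length(curve)],
                 train_config = train_config),
            class = "pte_vae")
}

#' @export
print.pte_vae <- function(x, ...) {
  cat("Slice-wise VAE:", paste(x$arch$input_size, collapse = "x"),
      "input, channels", paste(x$arch$channels, collapse = "/"),
      ", latent dim", x$arch$latent_dim, "\n")
  cat("  trained", length(x$curve), "epochs; loss",
      format(x$curve[1], digits = 4), "->",
      format(x$final_loss, digits = 4), "\n")
  invisible(x)
}

# Deterministic batched reconstruction (decode from the latent mean).
reconstruct_batch <- function(model, slices) {
  d <- dim(slices)
  x <- array(slices, c(d[1], d[2], 1, prod(d) / (d[1] * d[2])))
  geoms <- vae_geoms(model$arch)
  fw <- vae_forward(model$params, model$bn, geoms, model$arch, x,
                    training = FALSE, eps = NULL)
  array(fw$y, dim(slices))
}

#' Reconstruct a slice through the VAE
#'
#' Deterministic inference: the slice is encoded, the latent *mean* taken
#' (no sampling), and decoded. Same input, same output.
#'
#' @param model a trained `pte_vae`.
#' @param slice matrix matching the model's input size.
#' @return reconstructed slice of the same shape.
#' @export
reconstruct <- function(model, slice) {
  stopifnot(inherits(model, "pte_vae"))
  if (!all(dim(slice) == model$arch$input_size))
    stop("slice shape ", paste(dim(slice), collapse = "x"),
         " does not match model input size ",
         paste(model$arch$input_size, collapse = "x"))
  reconstruct_batch(model, array(slice, c(dim(slice), 1)))[, , 1]
}

#' @export
predict.pte_vae <- function(object, newdata, ...) reconstruct(object, newdata)

#' Collect brain-containing training slices from volumes
#'
#' Extracts every axial slice (third grid axis) whose nonzero fraction
#' exceeds `min_frac` and resizes it to `input_size` by bilinear
#' interpolation.
#'
#' @param volumes list of 3-D arrays.
#' @param input_size target slice dimensions.
#' @param min_frac minimum in-brain pixel fraction for a slice to be kept.
#' @return 3-D array (input_size x n_slices).
#' @export
training_slices <- function(volumes, input_size, min_frac = 0.05) {
  out <- list()
  for (v in volumes) {
    for (zi in seq_len(dim(v)[3])) {
      sl <- v[, , zi]
      if (mean(sl > 0) >= min_frac)
        out[[length(out) + 1]] <- resize_bilinear(sl, input_size)
    }
  }
  if (!length(out)) stop("no brain-containing slices found")
  array(unlist(out), c(input_size, length(out)))
}
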