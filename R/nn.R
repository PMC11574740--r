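# Minimal neural-network engine: im2col convolutions (stride-2 down- and
# up-sampling), batch normalization, dense layers, and Adam. Written in
# plain matrix algebra so every gradient can be checked against finite
# differences (see the test suite). Batches are arrays of dim (H, W, C, N).

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# ---- convolution geometry -------------------------------------------------
# A geometry describes a stride-`s` convolution from the "big" side
# (inH x inW x inC) to the "small" side (outH x outW) with `k x k` kernels
# and zero padding `pad`. A transposed convolution is the same geometry
# traversed in the opposite direction, so im2col/col2im serve both.

conv_geom <- function(inH, inW, inC, k, stride, pad) {
  outH <- (inH + 2 * pad - k) %/% stride + 1
  outW <- (inW + 2 * pad - k) %/% stride + 1
  g <- list(inH = inH, inW = inW, inC = inC, k = k, stride = stride,
            pad = pad, outH = outH, outW = outW,
            Hp = inH + 2 * pad, Wp = inW + 2 * pad,
            idx_cache = new.env(parent = emptyenv()))
  g
}

# Linear patch indices into the zero-padded input, rows = (position, image)
# with position fastest, cols = (dr, dc, channel). Cached per batch size.
geom_indices <- function(g, N) {
  key <- as.character(N)
  if (!is.null(g$idx_cache[[key]])) return(g$idx_cache[[key]])
  r0 <- (seq_len(g$outH) - 1) * g$stride + 1
  c0 <- (seq_len(g$outW) - 1) * g$stride + 1
  base <- outer(r0, (c0 - 1) * g$Hp, `+`)              # outH x outW
  off <- outer(0:(g$k - 1), (0:(g$k - 1)) * g$Hp, `+`) # k x k
  plane <- g$Hp * g$Wp
  # rows: positions for each image; add image/channel plane offsets
  pos <- as.vector(base)                                # outH*outW
  img_off <- (seq_len(N) - 1) * plane * g$inC
  rows <- as.vector(outer(pos, img_off, `+`))           # P*N
  ch_off <- (seq_len(g$inC) - 1) * plane
  cols <- as.vector(outer(as.vector(off), ch_off, `+`)) # k*k*inC
  idx <- outer(rows, cols, `+`)
  g$idx_cache[[key]] <- idx
  idx
}

pad_input <- function(x, g) {
  d <- dim(x); N <- d[4]
  if (g$pad == 0) return(x)
  xp <- array(0, c(g$Hp, g$Wp, g$inC, N))
  xp[g$pad + seq_len(g$inH), g$pad + seq_len(g$inW), , ] <- x
  xp
}

unpad_grad <- function(dxp, g) {
  if (g$pad == 0) return(dxp)
  dxp[g$pad + seq_len(g$inH), g$pad + seq_len(g$inW), , , drop = FALSE]
}

# im2col: (P*N) x (k*k*inC) patch matrix from a (H, W, C, N) batch.
im2col <- function(x, g) {
  N <- dim(x)[4]
  idx <- geom_indices(g, N)
  xp <- pad_input(x, g)
  m <- xp[idx]
  dim(m) <- dim(idx)
  m
}

# col2im: scatter-add a patch-matrix gradient back onto the padded input.
# Indices within one kernel-offset column are distinct positions, so the
# accumulation can run vectorized per column.
col2im <- function(dm, g, N) {
  idx <- geom_indices(g, N)
  dxp <- numeric(g$Hp * g$Wp * g$inC * N)
  for (j in seq_len(ncol(idx))) {
    ii <- idx[, j]
    dxp[ii] <- dxp[ii] + dm[, j]
  }
  dim(dxp) <- c(g$Hp, g$Wp, g$inC, N)
  unpad_grad(dxp, g)
}

# Reshape helpers between (outH, outW, F, N) arrays and (P*N) x F matrices
# whose rows are ordered position-fastest, image-slowest.
out_to_mat <- function(y) {
  d <- dim(y)  # outH outW F N
  m <- aperm(y, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}
mat_to_out <- function(m, outH, outW, N) {
  F <- ncol(m)
  dim(m) <- c(outH, outW, N, F)
  aperm(m, c(1, 2, 4, 3))
}

# Forward convolution: X (inH,inW,inC,N) -> (outH,outW,F,N).
conv_forward <- function(g, x, W, b) {
  N <- dim(x)[4]
  m <- im2col(x, g)
  y <- m %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = mat_to_out(y, g$outH, g$outW, N), m = m)
}

conv_backward <- function(g, cache_m, W, dy) {
  N <- dim(dy)[4]
  dym <- out_to_mat(dy)
  dW <- crossprod(cache_m, dym)
  db <- colSums(dym)
  dx <- col2im(tcrossprod(dym, W), g, N)
  list(dx = dx, dW = dW, db = db)
}

# Transposed convolution through the same geometry: input lives on the
# small side (outH,outW,Cin=F,N), output on the big side (inH,inW,inC,N).
deconv_forward <- function(g, x, W, b) {
  N <- dim(x)[4]
  xm <- out_to_mat(x)                   # (P*N) x F
  y <- col2im(tcrossprod(xm, W), g, N)  # big side, channels = g$inC
  y <- y + array(rep(b, each = g$inH * g$inW), dim(y))  # per-channel bias
  list(y = y, xm = xm)
}

deconv_backward <- function(g, cache_xm, W, dy) {
  N <- dim(dy)[4]
  m <- im2col(dy, g)                    # (P*N) x (k*k*inC)
  dx_m <- m %*% W                       # grads on the small side
  dW <- crossprod(m, cache_xm)
  db <- apply(dy, 3, sum)
  dx <- mat_to_out(dx_m, g$outH, g$outW, N)
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalization --------------------------------------------------
# Per-channel over batch and spatial positions; running statistics (for
# inference) are an exponential moving average initialized at first use.

bn_new <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C), seen = FALSE)
}

bn_forward <- function(bn, x, training = TRUE, momentum = 0.9, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  xm <- aperm(x, c(1, 2, 4, 3)); dim(xm) <- c(d[1] * d[2] * d[4], C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    if (!bn$seen) { bn$run_mean <- mu; bn$run_var <- v; bn$seen <- TRUE }
    else {
      bn$run_mean <- momentum * bn$run_mean + (1 - momentum) * mu
      bn$run_var <- momentum * bn$run_var + (1 - momentum) * v
    }
  } else {
    mu <- bn$run_mean; v <- bn$run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, `*`)
  ym <- sweep(sweep(xhat, 2, bn$gamma, `*`), 2, bn$beta, `+`)
  y <- ym; dim(y) <- c(d[1], d[2], d[4], C); y <- aperm(y, c(1, 2, 4, 3))
  list(y = y, bn = bn, xhat = xhat, inv = inv, dims = d)
}

bn_backward <- function(cache, dy) {
  d <- cache$dims; C <- d[3]
  dym <- aperm(dy, c(1, 2, 4, 3)); dim(dym) <- c(d[1] * d[2] * d[4], C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  gamma <- cache$bn$gamma
  m1 <- colMeans(dym)
  m2 <- colMeans(dym * xhat)
  dxm <- sweep(sweep(dym, 2, m1) - sweep(xhat, 2, m2, `*`),
               2, gamma * cache$inv, `*`)
  dx <- dxm; dim(dx) <- c(d[1], d[2], d[4], C); dx <- aperm(dx, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu <- function(x) { x[x < 0] <- 0; x }
relu_backward <- function(x_pre, dy) { dy[x_pre <= 0] <- 0; dy }
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- Adam -----------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}
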