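# Numerical core: 1-D conv / fully-connected / batch-norm / upsampling layers
# with explicit forward and backward passes, and the Adam optimizer.
#
# Layout conventions:
#   feature maps  : 3-D arrays (channels, length, batch)
#   conv weights  : C_out x (k * C_in), column r = (j-1)*C_in + c for tap j,
#                   input channel c (channel fastest)
#   fc weights    : n_out x n_in, acting on (n_in, batch) matrices
# Convolution is im2col + GEMM; the gather indices are precomputed per layer
# at build time (input lengths are fixed by the architecture).

EPS_BN <- 1e-5

# ---- geometry ----

conv_geom <- function(C_in, k, s, p, L_in) {
  list(L_out = conv_output_length(L_in, k, s, p), L_in = as.integer(L_in),
       k = as.integer(k), s = as.integer(s), p = as.integer(p))
}

# ---- activations ----

act_fwd <- function(Z, act, alpha = 0.2) {
  switch(act,
         none = Z,
         ReLU = Z * (Z > 0),
         LeakyReLU = Z * ((Z > 0) + alpha * (Z <= 0)),
         Tanh = tanh(Z),
         stop("unknown activation ", act))
}

act_bwd <- function(dY, Z, Y, act, alpha = 0.2) {
  switch(act,
         none = dY,
         ReLU = dY * (Z > 0),
         LeakyReLU = dY * ((Z > 0) + alpha * (Z <= 0)),
         Tanh = dY * (1 - Y * Y),
         stop("unknown activation ", act))
}

# Row-wise numerically stable softmax on a (n_class, B) logit matrix.
softmax_cols <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), "/")
}

# ---- parameter initialization ----

# N(0, 0.02): the initialization convention of this DCGAN-style network
# family; small initial logits keep the early adversarial game balanced.
init_weight <- function(n_out, n_in_eff, act) {
  matrix(stats::rnorm(n_out * n_in_eff, 0, 0.02), nrow = n_out)
}

# ---- conv layer ----

conv_forward <- function(W, b, geom, x, act, alpha, keep_cache = TRUE) {
  dm <- dim(x)                      # (C_in, L_in, B)
  C_in <- dm[1]; B <- dm[3]
  Xcol <- .im2col_pad(x, C_in, geom$L_in, B, geom$k, geom$s, geom$p,
                      geom$L_out)
  Z <- W %*% Xcol + b               # b length C_out recycles down columns
  Y <- act_fwd(Z, act, alpha)
  out <- array(Y, c(nrow(W), geom$L_out, B))
  if (!keep_cache) return(list(out = out))
  list(out = out, cache = list(Xcol = Xcol, Z = Z, Y = Y,
                               C_in = C_in, B = B))
}

conv_backward <- function(W, geom, cache, dout, act, alpha, need_dx = TRUE) {
  C_out <- nrow(W); B <- cache$B
  dY <- matrix(dout, nrow = C_out)
  dZ <- act_bwd(dY, cache$Z, cache$Y, act, alpha)
  dW <- dZ %*% t(cache$Xcol)
  db <- rowSums(dZ)
  if (!need_dx) return(list(dW = dW, db = db, dx = NULL))
  dXcol <- crossprod(W, dZ)
  dx <- .col2im_pad(dXcol, cache$C_in, geom$L_in, B, geom$k, geom$s, geom$p,
                    geom$L_out)
  list(dW = dW, db = db, dx = dx)
}

# ---- batch norm (per channel over length x batch) ----

bn_forward <- function(gamma, beta, rmean, rvar, momentum, x, train) {
  dm <- dim(x); C <- dm[1]; N <- dm[2] * dm[3]
  xm <- matrix(x, nrow = C)
  if (train) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + EPS_BN)
    xhat <- xc * inv
    # momentum = weight on the current batch statistic
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v * N / max(1, N - 1)
  } else {
    inv <- 1 / sqrt(rvar + EPS_BN)
    xhat <- (xm - rmean) * inv
  }
  y <- gamma * xhat + beta
  list(out = array(y, dm), cache = list(xhat = xhat, inv = inv, dm = dm),
       rmean = rmean, rvar = rvar)
}

bn_backward <- function(gamma, cache, dout) {
  C <- cache$dm[1]
  dy <- matrix(dout, nrow = C)
  dxhat <- dy * gamma
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dgamma = rowSums(dy * cache$xhat), dbeta = rowSums(dy),
       dx = array(dx, cache$dm))
}

# ---- nearest-neighbour upsampling ----

upsample_forward <- function(x, f) {
  L <- dim(x)[2]
  x[, rep(seq_len(L), each = f), , drop = FALSE]
}

upsample_backward <- function(dout, f) {
  Lf <- dim(dout)[2]
  Reduce(`+`, lapply(seq_len(f), function(o)
    dout[, seq(o, Lf, by = f), , drop = FALSE]))
}

# ---- Adam ----

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam step over a flat named parameter list. The update mutates the
# parameter and moment buffers in place (see src/adam.cpp); both are owned
# by the surrounding training loop, so the in-place semantics never leak.
adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  for (nm in names(params))
    .adam_update_inplace(params[[nm]], grads[[nm]], state$m[[nm]],
                         state$v[[nm]], lr_t, beta1, beta2, eps)
  list(params = params, state = state)
}
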