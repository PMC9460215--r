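# Trainable networks realizing the declarative architecture specs.
# A network is a list: spec, params (flat named list), buffers (batch-norm
# running statistics), geoms (precomputed conv gather indices), K,
# input_length. Forward passes accept row-per-sample matrices.

#' Instantiate the (K+1)-class convolutional classifier
#'
#' Allocates weights for [classifier_spec()] at the given frame length. The
#' four conv stages use He-style normal initialization; biases start at zero.
#'
#' @param K Number of real classes (default 2).
#' @param input_length Frame length; the conv chain requires roughly
#'   `input_length >= 600` so the fourth kernel-8 stage has valid placements.
#'   Default 10,000.
#' @param rng_seed Optional seed for weight initialization.
#' @return An object of class `ssgan_classifier`.
#' @export
build_classifier <- function(K = 2, input_length = 10000, rng_seed = NULL) {
  spec <- classifier_spec(K, input_length)
  with_rng(rng_seed, {
    chans <- c(1L, 64L, 64L, 64L, 1L)
    L <- input_length
    geoms <- list()
    params <- list()
    for (i in 1:4) {
      l <- spec$layers[[i]]
      geoms[[i]] <- conv_geom(chans[i], l$kernel, l$stride, l$padding, L)
      params[[paste0("c", i, ".W")]] <-
        init_weight(chans[i + 1], l$kernel * chans[i], "LeakyReLU")
      params[[paste0("c", i, ".b")]] <- numeric(chans[i + 1])
      L <- geoms[[i]]$L_out
    }
    params[["fc.W"]] <- init_weight(K + 1L, L, "none")
    params[["fc.b"]] <- numeric(K + 1L)
    structure(list(spec = spec, params = params, buffers = list(),
                   geoms = geoms, K = as.integer(K),
                   input_length = as.integer(input_length), flat_len = L,
                   trained = FALSE),
              class = "ssgan_classifier")
  })
}

classifier_forward_internal <- function(net, X, keep_cache = FALSE) {
  stopifnot(ncol(X) == net$input_length)
  B <- nrow(X)
  x <- array(t(X), c(1L, net$input_length, B))
  caches <- vector("list", 4)
  for (i in 1:4) {
    l <- net$spec$layers[[i]]
    r <- conv_forward(net$params[[paste0("c", i, ".W")]],
                      net$params[[paste0("c", i, ".b")]],
                      net$geoms[[i]], x, l$activation, l$alpha,
                      keep_cache = keep_cache)
    x <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  flat <- matrix(x, nrow = net$flat_len)             # last conv has 1 channel
  logits <- net$params[["fc.W"]] %*% flat + net$params[["fc.b"]]
  probs <- softmax_cols(logits)
  list(probs = t(probs), logits = logits,
       cache = if (keep_cache) list(convs = caches, flat = flat, B = B))
}

# dlogits: (K+1, B). Returns flat grads and optionally dX (B x L matrix).
classifier_backward_internal <- function(net, cache, dlogits, need_dx = FALSE) {
  grads <- list()
  grads[["fc.W"]] <- dlogits %*% t(cache$flat)
  grads[["fc.b"]] <- rowSums(dlogits)
  dflat <- crossprod(net$params[["fc.W"]], dlogits)
  dx <- array(dflat, c(1L, net$flat_len, cache$B))
  for (i in 4:1) {
    l <- net$spec$layers[[i]]
    r <- conv_backward(net$params[[paste0("c", i, ".W")]], net$geoms[[i]],
                       cache$convs[[i]], dx, l$activation, l$alpha,
                       need_dx = need_dx || i > 1)
    grads[[paste0("c", i, ".W")]] <- r$dW
    grads[[paste0("c", i, ".b")]] <- r$db
    dx <- r$dx
  }
  list(grads = grads,
       dX = if (need_dx) t(matrix(dx, nrow = net$input_length)))
}

#' Classify spectral frames
#'
#' Runs the classifier forward and returns one probability row per frame over
#' the K+1 classes (indices: the K real classes in label order, then the
#' generated/fake class last). Rows are non-negative and sum to 1.
#'
#' @param net An `ssgan_classifier` (from [build_classifier()] or
#'   [train_ssgan()]).
#' @param frames A `frame_set` of spectral frames, or a numeric matrix with
#'   one frame per row.
#' @param chunk Frames are processed in chunks of this many rows to bound
#'   memory.
#' @return A numeric matrix, `n_frames x (K+1)`.
#' @export
forward_classifier <- function(net, frames, chunk = 64L) {
  stopifnot(inherits(net, "ssgan_classifier"))
  X <- if (inherits(frames, "frame_set")) frames$values else as.matrix(frames)
  if (ncol(X) != net$input_length)
    stop("frame length ", ncol(X), " does not match the classifier input ",
         net$input_length, call. = FALSE)
  out <- matrix(NA_real_, nrow(X), net$K + 1L)
  for (s in seq(1L, nrow(X), by = chunk)) {
    i <- s:min(nrow(X), s + chunk - 1L)
    out[i, ] <- classifier_forward_internal(net, X[i, , drop = FALSE])$probs
  }
  out
}

#' Instantiate the generator
#'
#' Allocates weights for [generator_spec()] at the given frame length: a
#' dense projection from the noise vector to `16 * input_length` units
#' (reshaped to 64 channels), two upsample+conv+batch-norm stages, and the
#' final Tanh convolution. Note the parameter count of the dense projection
#' grows quadratically with `input_length` (1.6e9 weights at the reference
#' length 10,000), so instantiated generators are intended for reduced frame
#' lengths; the reference-scale architecture itself is validated
#' declaratively via [trace_shapes()].
#'
#' @inheritParams build_classifier
#' @return An object of class `ssgan_generator`.
#' @export
build_generator <- function(input_length = 1000, rng_seed = NULL) {
  spec <- generator_spec(input_length)
  with_rng(rng_seed, {
    L <- as.integer(input_length)
    l4 <- L %/% 4L
    geoms <- list(
      conv1 = conv_geom(64L, 3L, 1L, 1L, l4 * 2L),
      conv2 = conv_geom(64L, 3L, 1L, 1L, L),
      conv3 = conv_geom(32L, 3L, 1L, 1L, L)
    )
    params <- list(
      "fc.W" = init_weight(16L * L, L, "ReLU"),
      "fc.b" = numeric(16L * L),
      "g1.W" = init_weight(64L, 3L * 64L, "ReLU"),
      "g1.b" = numeric(64L),
      "bn1.gamma" = rep(1, 64L), "bn1.beta" = numeric(64L),
      "g2.W" = init_weight(32L, 3L * 64L, "ReLU"),
      "g2.b" = numeric(32L),
      "bn2.gamma" = rep(1, 32L), "bn2.beta" = numeric(32L),
      "g3.W" = init_weight(1L, 3L * 32L, "Tanh"),
      "g3.b" = numeric(1L)
    )
    buffers <- list(
      "bn1.rmean" = numeric(64L), "bn1.rvar" = rep(1, 64L),
      "bn2.rmean" = numeric(32L), "bn2.rvar" = rep(1, 32L)
    )
    structure(list(spec = spec, params = params, buffers = buffers,
                   geoms = geoms, input_length = L, momentum = 0.8),
              class = "ssgan_generator")
  })
}

generator_forward_internal <- function(net, Z, train = FALSE,
                                       keep_cache = FALSE) {
  stopifnot(ncol(Z) == net$input_length)
  B <- nrow(Z); L <- net$input_length; l4 <- L %/% 4L
  Zt <- t(Z)                                        # (L, B)
  # the dense projection has no activation; nonlinearity starts at conv1
  fc_lin <- net$params[["fc.W"]] %*% Zt + net$params[["fc.b"]]
  h <- array(fc_lin, c(64L, l4, B))
  u1 <- upsample_forward(h, 2L)
  r1 <- conv_forward(net$params[["g1.W"]], net$params[["g1.b"]],
                     net$geoms$conv1, u1, "ReLU", NA, keep_cache)
  b1 <- bn_forward(net$params[["bn1.gamma"]], net$params[["bn1.beta"]],
                   net$buffers[["bn1.rmean"]], net$buffers[["bn1.rvar"]],
                   net$momentum, r1$out, train)
  u2 <- upsample_forward(b1$out, 2L)
  r2 <- conv_forward(net$params[["g2.W"]], net$params[["g2.b"]],
                     net$geoms$conv2, u2, "ReLU", NA, keep_cache)
  b2 <- bn_forward(net$params[["bn2.gamma"]], net$params[["bn2.beta"]],
                   net$buffers[["bn2.rmean"]], net$buffers[["bn2.rvar"]],
                   net$momentum, r2$out, train)
  r3 <- conv_forward(net$params[["g3.W"]], net$params[["g3.b"]],
                     net$geoms$conv3, b2$out, "Tanh", NA, keep_cache)
  out <- t(matrix(r3$out, nrow = L))                # (B, L)
  buffers <- net$buffers
  if (train) {
    buffers[["bn1.rmean"]] <- b1$rmean; buffers[["bn1.rvar"]] <- b1$rvar
    buffers[["bn2.rmean"]] <- b2$rmean; buffers[["bn2.rvar"]] <- b2$rvar
  }
  list(out = out, buffers = buffers,
       cache = if (keep_cache)
         list(Zt = Zt, fc_lin = fc_lin, c1 = r1$cache, bn1 = b1$cache,
              c2 = r2$cache, bn2 = b2$cache, c3 = r3$cache, B = B))
}

generator_backward_internal <- function(net, cache, dOut) {
  L <- net$input_length; B <- cache$B
  grads <- list()
  dx <- array(t(dOut), c(1L, L, B))
  r3 <- conv_backward(net$params[["g3.W"]], net$geoms$conv3, cache$c3, dx,
                      "Tanh", NA)
  grads[["g3.W"]] <- r3$dW; grads[["g3.b"]] <- r3$db
  b2 <- bn_backward(net$params[["bn2.gamma"]], cache$bn2, r3$dx)
  grads[["bn2.gamma"]] <- b2$dgamma; grads[["bn2.beta"]] <- b2$dbeta
  r2 <- conv_backward(net$params[["g2.W"]], net$geoms$conv2, cache$c2, b2$dx,
                      "ReLU", NA)
  grads[["g2.W"]] <- r2$dW; grads[["g2.b"]] <- r2$db
  du2 <- upsample_backward(r2$dx, 2L)
  b1 <- bn_backward(net$params[["bn1.gamma"]], cache$bn1, du2)
  grads[["bn1.gamma"]] <- b1$dgamma; grads[["bn1.beta"]] <- b1$dbeta
  r1 <- conv_backward(net$params[["g1.W"]], net$geoms$conv1, cache$c1, b1$dx,
                      "ReLU", NA)
  grads[["g1.W"]] <- r1$dW; grads[["g1.b"]] <- r1$db
  du1 <- upsample_backward(r1$dx, 2L)
  dfc <- matrix(du1, nrow = 16L * L)
  grads[["fc.W"]] <- dfc %*% t(cache$Zt)
  grads[["fc.b"]] <- rowSums(dfc)
  grads
}

#' Generate fake spectral frames from noise
#'
#' Runs the generator forward in inference mode (batch-norm uses running
#' statistics). Output rows have the spectral-frame shape and, through the
#' final Tanh, lie in \[-1, 1\]; the pass is deterministic given weights and
#' noise.
#'
#' @param net An `ssgan_generator`.
#' @param noise A matrix of standard-normal noise, one row per sample, with
#'   `ncol == input_length` (see [draw_noise()]).
#' @return A numeric matrix of generated frames, same shape as `noise`.
#' @export
forward_generator <- function(net, noise) {
  stopifnot(inherits(net, "ssgan_generator"))
  noise <- as.matrix(noise)
  if (ncol(noise) != net$input_length)
    stop("noise length ", ncol(noise), " does not match the generator input ",
         net$input_length, call. = FALSE)
  generator_forward_internal(net, noise, train = FALSE)$out
}
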