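#' Training configuration for the SSGAN
#'
#' Defaults follow the study settings: learning rate 0.002, 100 epochs,
#' mini-batches of 10, Adam. Adam's moment decays (0.5, 0.999) are the usual
#' stabilization for adversarial training. `clamp_eps` bounds every
#' probability entering a log away from the simplex boundary, capping each
#' loss term at `-log(clamp_eps)`.
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs Number of passes over the labeled pool (>= 1).
#' @param batch_size Examples per stream per step (>= 1); each classifier
#'   step sees one labeled, one unlabeled and one generated batch of this
#'   size.
#' @param K Number of real classes (default 2).
#' @param beta1,beta2 Adam moment decays.
#' @param clamp_eps Probability clamp inside logs.
#' @param generator_every Update the generator once every this many
#'   classifier steps (default 1, i.e. strictly alternating updates).
#' @param seed Integer seed making the whole run reproducible; `NULL` uses
#'   the ambient RNG stream.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.002, epochs = 100, batch_size = 10,
                         K = 2, beta1 = 0.5, beta2 = 0.999, clamp_eps = 1e-7,
                         generator_every = 1, seed = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1, K >= 1,
            clamp_eps > 0, clamp_eps < 0.5, generator_every >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), K = as.integer(K),
                 beta1 = beta1, beta2 = beta2, clamp_eps = clamp_eps,
                 generator_every = as.integer(generator_every), seed = seed),
            class = "train_config")
}

check_simplex <- function(probs, what = "probabilities") {
  probs <- as.matrix(probs)
  if (nrow(probs) == 0) return(probs)
  if (any(!is.finite(probs)) || any(probs < -1e-9) ||
      any(abs(rowSums(probs) - 1) > 1e-6))
    stop(what, " must be rows of a probability simplex", call. = FALSE)
  probs
}

clamp_p <- function(p, eps) pmin(1 - eps, pmax(eps, p))

#' Supervised classifier loss (cross-entropy over the real classes)
#'
#' Mean negative log-probability assigned to the true label, evaluated on
#' labeled real examples only. Labels are the real classes `0..K-1`; the
#' fake class (index K) never appears as a truth label.
#'
#' @param probs Matrix of K+1-class probability rows.
#' @param labels Integer labels in `0..K-1`, one per row.
#' @param eps Probability clamp (see [train_config()]).
#' @return Non-negative scalar (nats).
#' @export
supervised_loss <- function(probs, labels, eps = 1e-7) {
  probs <- check_simplex(probs)
  K <- ncol(probs) - 1L
  if (nrow(probs) != length(labels)) stop("one label per row required",
                                          call. = FALSE)
  if (any(labels < 0 | labels >= K))
    stop("labels must be real classes 0..K-1 (fake index forbidden)",
         call. = FALSE)
  p_true <- probs[cbind(seq_len(nrow(probs)), labels + 1L)]
  mean(-log(clamp_p(p_true, eps)))
}

#' Unsupervised (real-vs-fake) classifier loss
#'
#' Mean over real examples of `-log(1 - p_fake(x))` plus mean over generated
#' examples of `-log(p_fake(G(z)))`, where `p_fake` is the probability mass
#' on the last (generated) class. An empty real batch drops its term, so the
#' loss reduces to the fake term alone.
#'
#' @param real_probs Probability rows for real (unlabeled) examples; may have
#'   zero rows.
#' @param fake_probs Probability rows for generated examples.
#' @param eps Probability clamp.
#' @return Non-negative scalar (nats).
#' @export
unsupervised_loss <- function(real_probs, fake_probs, eps = 1e-7) {
  real_probs <- check_simplex(real_probs, "real probabilities")
  fake_probs <- check_simplex(fake_probs, "fake probabilities")
  if (nrow(fake_probs) == 0 && nrow(real_probs) == 0)
    stop("both batches empty", call. = FALSE)
  term_real <- if (nrow(real_probs) > 0) {
    s <- real_probs[, ncol(real_probs)]
    mean(-log(clamp_p(1 - s, eps)))
  } else 0
  term_fake <- if (nrow(fake_probs) > 0) {
    s <- fake_probs[, ncol(fake_probs)]
    mean(-log(clamp_p(s, eps)))
  } else 0
  term_real + term_fake
}

#' Generator loss
#'
#' The generator is rewarded when its output is classified as any real
#' class: `-mean(log(1 - p_fake(G(z))))`, the real-mass direction of the
#' adversarial objective. Zero when the classifier assigns the fakes no fake
#' mass; capped at `-log(eps)` as `p_fake` approaches 1.
#'
#' @param fake_probs Probability rows for generated examples.
#' @param eps Probability clamp.
#' @return Non-negative scalar (nats).
#' @export
generator_loss <- function(fake_probs, eps = 1e-7) {
  fake_probs <- check_simplex(fake_probs, "fake probabilities")
  if (nrow(fake_probs) == 0) stop("empty batch", call. = FALSE)
  s <- fake_probs[, ncol(fake_probs)]
  mean(-log(clamp_p(1 - s, eps)))
}

# Gradient of -log(sum of real-class probs) w.r.t. logits, per column of a
# (K+1, B) probability matrix; divided by B (mean loss).
dlogits_real_mass <- function(P, eps) {
  B <- ncol(P)
  p_real <- clamp_p(1 - P[nrow(P), ], eps)
  D <- P
  D[-nrow(D), ] <- sweep(P[-nrow(P), , drop = FALSE], 2,
                         1 / p_real, "*") * -1 + P[-nrow(P), , drop = FALSE]
  # row j < fake: p_j - p_j / p_real ; fake row: p_fake
  D / B
}

# Gradient of -log(p_fake) w.r.t. logits (= softmax CE with target fake).
dlogits_fake_mass <- function(P) {
  B <- ncol(P)
  Y <- matrix(0, nrow(P), B); Y[nrow(P), ] <- 1
  (P - Y) / B
}

#' Train the semi-supervised GAN
#'
#' Alternates, per mini-batch: (i) a classifier step minimizing
#' `Loss = L1 + L2` -- supervised cross-entropy on a labeled batch plus the
#' real-vs-fake term on an unlabeled batch and a freshly generated batch --
#' and (ii) a generator step minimizing [generator_loss()] through the
#' frozen classifier. One epoch is one pass over the labeled pool. The run
#' is bit-reproducible under `config$seed`.
#'
#' @param labeled `frame_set` of labeled spectral frames (every class
#'   `0..K-1` must be present).
#' @param unlabeled Optional `frame_set` of unlabeled spectral frames; if
#'   `NULL` or empty, the unsupervised term uses generated batches only.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `ssgan_fit`: list with `classifier`,
#'   `generator`, `history` (per-epoch data frame of `L1`, `L2`,
#'   `loss = L1 + L2`, `g_loss`), and `config`.
#' @export
train_ssgan <- function(labeled, unlabeled = NULL, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(labeled, "frame_set"), inherits(config, "train_config"))
  if (length(labeled) == 0) stop("empty labeled set", call. = FALSE)
  y <- labeled$label
  if (any(is.na(y))) stop("labeled pool contains unlabeled frames",
                          call. = FALSE)
  missing_cl <- setdiff(0:(config$K - 1), unique(y))
  if (length(missing_cl))
    stop("class(es) absent from labels: ", paste(missing_cl, collapse = ", "),
         call. = FALSE)
  L <- ncol(labeled$values)
  Xu <- if (!is.null(unlabeled) && length(unlabeled) > 0)
    unlabeled$values else NULL

  with_rng(config$seed, {
    clf <- build_classifier(config$K, L)
    gen <- build_generator(L)
    st_c <- adam_init(clf$params)
    st_g <- adam_init(gen$params)
    n <- length(labeled)
    bs <- min(config$batch_size, n)
    eps <- config$clamp_eps
    fake_col <- config$K + 1L
    history <- vector("list", config$epochs)

    for (epoch in seq_len(config$epochs)) {
      perm <- sample(n)
      steps <- max(1L, n %/% bs)
      rec <- matrix(0, steps, 4)
      for (s in seq_len(steps)) {
        li <- perm[((s - 1L) * bs + 1L):min(n, s * bs)]
        Xl <- labeled$values[li, , drop = FALSE]
        yl <- y[li]
        Xub <- if (!is.null(Xu))
          Xu[sample(nrow(Xu), bs, replace = nrow(Xu) < bs), , drop = FALSE]
        gz <- generator_forward_internal(
          gen, matrix(stats::rnorm(bs * L), bs), train = TRUE,
          keep_cache = TRUE)
        gen$buffers <- gz$buffers
        Xf <- gz$out

        X <- rbind(Xl, if (!is.null(Xub)) Xub, Xf)
        fw <- classifier_forward_internal(clf, X, keep_cache = TRUE)
        P <- t(fw$probs)                        # (K+1, B_total)
        nl <- length(li); nu <- if (is.null(Xub)) 0L else nrow(Xub)
        i_l <- seq_len(nl)
        i_u <- if (nu > 0) nl + seq_len(nu) else integer(0)
        i_f <- (nl + nu) + seq_len(bs)

        L1 <- supervised_loss(fw$probs[i_l, , drop = FALSE], yl, eps)
        L2 <- unsupervised_loss(fw$probs[i_u, , drop = FALSE],
                                fw$probs[i_f, , drop = FALSE], eps)

        dlog <- matrix(0, fake_col, nrow(X))
        onehot <- matrix(0, fake_col, nl)
        onehot[cbind(yl + 1L, seq_len(nl))] <- 1
        dlog[, i_l] <- (P[, i_l, drop = FALSE] - onehot) / nl
        if (nu > 0)
          dlog[, i_u] <- dlogits_real_mass(P[, i_u, drop = FALSE], eps)
        dlog[, i_f] <- dlogits_fake_mass(P[, i_f, drop = FALSE])

        bw <- classifier_backward_internal(clf, fw$cache, dlog)
        up <- adam_step(clf$params, bw$grads, st_c, config$learning_rate,
                        config$beta1, config$beta2)
        clf$params <- up$params; st_c <- up$state

        # generator step (every generator_every classifier steps): the same
        # fake batch, scored by the (frozen) just-updated classifier
        gl <- generator_loss(fw$probs[i_f, , drop = FALSE], eps)
        if (s %% config$generator_every == 0L) {
          fw2 <- classifier_forward_internal(clf, Xf, keep_cache = TRUE)
          gl <- generator_loss(fw2$probs, eps)
          dlog_g <- dlogits_real_mass(t(fw2$probs), eps)
          bw2 <- classifier_backward_internal(clf, fw2$cache, dlog_g,
                                              need_dx = TRUE)
          ggr <- generator_backward_internal(gen, gz$cache, bw2$dX)
          upg <- adam_step(gen$params, ggr, st_g, config$learning_rate,
                           config$beta1, config$beta2)
          gen$params <- upg$params; st_g <- upg$state
        }

        rec[s, ] <- c(L1, L2, L1 + L2, gl)
      }
      m <- colMeans(rec)
      history[[epoch]] <- data.frame(epoch = epoch, L1 = m[1], L2 = m[2],
                                     loss = m[1] + m[2], g_loss = m[4])
      if (verbose)
        message(sprintf("epoch %3d  L1 %.4f  L2 %.4f  loss %.4f  G %.4f",
                        epoch, m[1], m[2], m[1] + m[2], m[4]))
    }
    clf$trained <- TRUE
    structure(list(classifier = clf, generator = gen,
                   history = do.call(rbind, history), config = config),
              class = "ssgan_fit")
  })
}

#' @export
print.ssgan_fit <- function(x, ...) {
  h <- utils::tail(x$history, 1)
  cat(sprintf(paste0("<ssgan_fit> %d epochs, frame length %d; final losses: ",
                     "L1 %.4f, L2 %.4f, G %.4f\n"),
              nrow(x$history), x$classifier$input_length, h$L1, h$L2, h$g_loss))
  invisible(x)
}

#' Train the plain CNN baseline
#'
#' A fully supervised reference model with the same convolutional topology
#' as the SSGAN classifier but a 2-neuron softmax head, trained with
#' ordinary cross-entropy under the same optimizer settings. Serves as the
#' labeled-data-only comparison point.
#'
#' @inheritParams train_ssgan
#' @return An object of class `cnn_fit`: list with `classifier` (head size
#'   2), `history`, `config`.
#' @export
train_cnn_baseline <- function(labeled, config = train_config(),
                               verbose = FALSE) {
  stopifnot(inherits(labeled, "frame_set"), inherits(config, "train_config"))
  if (length(labeled) == 0) stop("empty labeled set", call. = FALSE)
  y <- labeled$label
  if (any(is.na(y))) stop("labeled pool contains unlabeled frames",
                          call. = FALSE)
  L <- ncol(labeled$values)
  with_rng(config$seed, {
    # K = 1 instantiates the same conv stack with a 2-output head; the two
    # outputs are used as the two real classes here.
    clf <- build_classifier(1L, L)
    st <- adam_init(clf$params)
    n <- length(labeled)
    bs <- min(config$batch_size, n)
    eps <- config$clamp_eps
    history <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample(n)
      steps <- max(1L, n %/% bs)
      losses <- numeric(steps)
      for (s in seq_len(steps)) {
        li <- perm[((s - 1L) * bs + 1L):min(n, s * bs)]
        fw <- classifier_forward_internal(clf, labeled$values[li, , drop = FALSE],
                                          keep_cache = TRUE)
        P <- t(fw$probs)
        onehot <- matrix(0, 2L, length(li))
        onehot[cbind(y[li] + 1L, seq_along(li))] <- 1
        losses[s] <- mean(-log(clamp_p(P[cbind(y[li] + 1L, seq_along(li))],
                                       eps)))
        bw <- classifier_backward_internal(clf, fw$cache,
                                           (P - onehot) / length(li))
        up <- adam_step(clf$params, bw$grads, st, config$learning_rate,
                        config$beta1, config$beta2)
        clf$params <- up$params; st <- up$state
      }
      history[[epoch]] <- data.frame(epoch = epoch, loss = mean(losses))
      if (verbose) message(sprintf("epoch %3d  CE %.4f", epoch, mean(losses)))
    }
    clf$trained <- TRUE
    structure(list(classifier = clf, history = do.call(rbind, history),
                   config = config),
              class = "cnn_fit")
  })
}
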