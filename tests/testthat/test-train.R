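simplex3 <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  m / rowSums(m)
}

test_that("supervised loss matches closed forms", {
  expect_lt(supervised_loss(matrix(c(1, 0, 0), 1), 0L), 1e-5)
  expect_equal(supervised_loss(matrix(1 / 3, 1, 3), 1L), log(3),
               tolerance = 1e-9)
  p <- simplex3(0.5, 0.3, 0.2,
                0.25, 0.5, 0.25)
  expect_equal(supervised_loss(p, c(0L, 0L)), (log(2) + log(4)) / 2,
               tolerance = 1e-9)
  expect_error(supervised_loss(p, c(0L, 2L)), "fake index")
  expect_error(supervised_loss(matrix(c(0.9, 0.9, 0.9), 1), 0L), "simplex")
})

test_that("unsupervised loss matches closed forms and clamps at the ceiling", {
  perfect_real <- matrix(c(0.6, 0.4, 0), 1)
  perfect_fake <- matrix(c(0, 0, 1), 1)
  expect_lt(unsupervised_loss(perfect_real, perfect_fake), 1e-5)
  half <- matrix(c(0.25, 0.25, 0.5), 1)
  expect_equal(unsupervised_loss(half, half), 2 * log(2), tolerance = 1e-9)
  # p_fake -> 1 on real data diverges; the clamp caps it at -log(eps)
  diverged <- unsupervised_loss(perfect_fake, perfect_fake, eps = 1e-7)
  expect_equal(diverged, -log(1e-7), tolerance = 1e-6)
  # empty real batch leaves the fake term alone
  none <- matrix(numeric(0), 0, 3)
  expect_equal(unsupervised_loss(none, half), log(2), tolerance = 1e-9)
  expect_error(unsupervised_loss(none, none), "empty")
})

test_that("generator loss matches closed forms", {
  expect_lt(generator_loss(matrix(c(0.7, 0.3, 0), 1)), 1e-5)
  expect_equal(generator_loss(matrix(c(0.25, 0.25, 0.5), 1)), log(2),
               tolerance = 1e-9)
  expect_equal(generator_loss(matrix(c(0, 0, 1), 1), eps = 1e-7),
               -log(1e-7), tolerance = 1e-6)
})

test_that("loss gradients match the losses (finite differences on logits)", {
  set.seed(8)
  logits <- matrix(rnorm(3 * 4), 3)
  P <- bowelwarn:::softmax_cols(logits)
  h <- 1e-6
  # real-mass direction used for unlabeled data and the generator objective
  ana <- bowelwarn:::dlogits_real_mass(P, 1e-7)
  for (idx in sample(12, 6)) {
    lp <- logits; lp[idx] <- lp[idx] + h
    lm <- logits; lm[idx] <- lm[idx] - h
    f <- function(l) mean(-log(pmax(1e-12,
      1 - bowelwarn:::softmax_cols(l)[3, ])))
    expect_equal(ana[idx], (f(lp) - f(lm)) / (2 * h), tolerance = 1e-4)
  }
  anaf <- bowelwarn:::dlogits_fake_mass(P)
  for (idx in sample(12, 6)) {
    lp <- logits; lp[idx] <- lp[idx] + h
    lm <- logits; lm[idx] <- lm[idx] - h
    f <- function(l) mean(-log(bowelwarn:::softmax_cols(l)[3, ]))
    expect_equal(anaf[idx], (f(lp) - f(lm)) / (2 * h), tolerance = 1e-4)
  }
})

make_tiny_frames <- function(n, L = 640, seed = 1) {
  generate_fixture_set(synth_config_separated(L), n, n %/% 2, rng_seed = seed,
                       window = L)
}

test_that("training is bit-reproducible under a fixed seed", {
  lab <- make_tiny_frames(20)
  cfg <- train_config(epochs = 2, seed = 77)
  f1 <- train_ssgan(lab, NULL, cfg)
  f2 <- train_ssgan(lab, NULL, cfg)
  expect_identical(f1$history, f2$history)
  probe <- make_tiny_frames(6, seed = 9)
  expect_identical(predict_segments(f1, probe), predict_segments(f2, probe))
})

test_that("reported Loss decomposes exactly as L1 + L2 and terms are non-negative", {
  lab <- make_tiny_frames(20)
  unl <- make_tiny_frames(10, seed = 2)
  unl$label <- rep(NA_integer_, 10)
  fit <- train_ssgan(lab, unl, train_config(epochs = 3, seed = 5))
  h <- fit$history
  expect_equal(h$loss, h$L1 + h$L2, tolerance = 0)
  expect_true(all(h$L1 >= 0))
  expect_true(all(h$L2 >= 0))
  expect_true(all(h$g_loss >= 0))
})

test_that("a single small-step classifier update does not increase the batch loss", {
  lab <- make_tiny_frames(10)
  clf <- build_classifier(2, 640, rng_seed = 3)
  loss_of <- function(net) {
    fw <- bowelwarn:::classifier_forward_internal(net, lab$values)
    supervised_loss(fw$probs, lab$label)
  }
  before <- loss_of(clf)
  fw <- bowelwarn:::classifier_forward_internal(clf, lab$values,
                                                keep_cache = TRUE)
  P <- t(fw$probs)
  onehot <- matrix(0, 3, 10); onehot[cbind(lab$label + 1L, 1:10)] <- 1
  bw <- bowelwarn:::classifier_backward_internal(clf, fw$cache,
                                                 (P - onehot) / 10)
  st <- bowelwarn:::adam_init(clf$params)
  bowelwarn:::adam_step(clf$params, bw$grads, st, lr = 1e-4)
  expect_lte(loss_of(clf), before)
})

test_that("training requires labels for every class", {
  lab <- make_tiny_frames(20)
  expect_error(train_ssgan(subset_frames(lab, integer(0)), NULL,
                           train_config(epochs = 1)), "empty")
  only0 <- subset_frames(lab, which(lab$label == 0))
  expect_error(train_ssgan(only0, NULL, train_config(epochs = 1)), "absent")
})

test_that("the CNN baseline has a 2-class head, is seeded, and learns separable data", {
  lab <- make_tiny_frames(60, seed = 21)
  cfg <- train_config(epochs = 10, seed = 31)
  fit <- train_cnn_baseline(lab, cfg)
  probs <- forward_classifier(fit$classifier, subset_frames(lab, 1:4))
  expect_identical(ncol(probs), 2L)
  fit2 <- train_cnn_baseline(lab, cfg)
  expect_identical(fit$history, fit2$history)
  held <- make_tiny_frames(40, seed = 22)
  acc <- accuracy(confusion(predict_segments(fit, held), held$label))
  expect_gt(acc, 0.7)
})
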