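test_that("conv_output_length reproduces the printed classifier chain", {
  expect_identical(conv_output_length(10000, 8, 4, 2), 2500L)
  expect_identical(conv_output_length(2500, 8, 4, 0), 624L)
  expect_identical(conv_output_length(624, 8, 4, 0), 155L)
  expect_identical(conv_output_length(155, 8, 4, 0), 37L)
  expect_identical(conv_output_length(5, 5, 1, 0), 1L)
  expect_error(conv_output_length(4, 5, 1, 0), "larger than")
})

test_that("conv_output_length agrees with brute-force placement enumeration", {
  set.seed(3)
  for (i in 1:200) {
    L <- sample(1:64, 1); k <- sample(1:16, 1)
    s <- sample(1:8, 1); p <- sample(0:4, 1)
    if (k > L + 2 * p) {
      expect_error(conv_output_length(L, k, s, p))
    } else {
      expect_identical(conv_output_length(L, k, s, p),
                       count_placements(L, k, s, p),
                       info = sprintf("L=%d k=%d s=%d p=%d", L, k, s, p))
    }
  }
})

test_that("generator spec traces to the printed layer shapes", {
  tr <- trace_shapes(generator_spec())
  main <- tr[tr$layer_type != "batch_norm", ]
  expect_identical(main$out_length, c(2500L, 5000L, 5000L, 10000L, 10000L,
                                      10000L))
  expect_identical(main$out_channels, c(64L, 64L, 64L, 64L, 32L, 1L))
  # dense projection emits 160,000 values before the reshape
  expect_identical(main$out_length[1] * main$out_channels[1], 160000L)
  last <- tr[nrow(tr), ]
  expect_identical(last$activation, "Tanh")
  # batch-norm rows leave shapes untouched
  expect_identical(tr$out_length[4], tr$out_length[3])
})

test_that("classifier spec traces to the printed layer shapes and K+1 head", {
  tr <- trace_shapes(classifier_spec(K = 2))
  expect_identical(tr$out_length[1:4], c(2500L, 624L, 155L, 37L))
  expect_identical(tr$out_channels[1:4], c(64L, 64L, 64L, 1L))
  expect_identical(tr$out_channels[5], 3L)
  expect_identical(tr$activation[5], "Softmax")
  expect_true(all(tr$activation[1:4] == "LeakyReLU"))
  expect_identical(trace_shapes(classifier_spec(K = 1))$out_channels[5], 2L)
  expect_error(classifier_spec(K = 0), "K")
})

test_that("architecture specs survive a YAML round trip and match the checked-in transcription", {
  for (mk in list(generator_spec, classifier_spec)) {
    spec <- mk()
    back <- arch_from_yaml(arch_to_yaml(spec))
    expect_identical(trace_shapes(back), trace_shapes(spec))
    expect_identical(back$name, spec$name)
  }
  ref <- arch_from_yaml(system.file("extdata", "classifier-reference.yaml",
                                    package = "bowelwarn"))
  expect_identical(trace_shapes(ref), trace_shapes(classifier_spec()))
  ref_g <- arch_from_yaml(system.file("extdata", "generator-reference.yaml",
                                      package = "bowelwarn"))
  expect_identical(trace_shapes(ref_g), trace_shapes(generator_spec()))
})

test_that("softmax closed forms hold", {
  u <- bowelwarn:::softmax_cols(matrix(c(5, 5, 5)))
  expect_equal(as.vector(u), rep(1 / 3, 3), tolerance = 1e-12)
  v <- bowelwarn:::softmax_cols(matrix(c(log(2), 0, 0)))
  expect_equal(as.vector(v), c(0.5, 0.25, 0.25), tolerance = 1e-12)
})

test_that("classifier outputs are simplex points for arbitrary finite frames", {
  clf <- build_classifier(2, 640, rng_seed = 1)
  set.seed(2)
  for (i in 1:8) {
    X <- matrix(rnorm(3 * 640, sd = 10^runif(1, -4, 4)), 3)
    P <- forward_classifier(clf, X)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-9)
  }
  expect_error(forward_classifier(clf, matrix(0, 2, 100)), "does not match")
})

test_that("classifier instantiates and runs at the reference frame length", {
  clf <- build_classifier(2, 10000, rng_seed = 4)
  P <- forward_classifier(clf, matrix(rnorm(2 * 10000), 2))
  expect_identical(dim(P), c(2L, 3L))
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-9)
})

test_that("generator output is Tanh-bounded, frame-shaped and deterministic", {
  gen <- build_generator(640, rng_seed = 5)
  z <- draw_noise(4, 640, rng_seed = 6)
  a <- forward_generator(gen, z)
  b <- forward_generator(gen, z)
  expect_identical(a, b)
  expect_identical(dim(a), c(4L, 640L))
  expect_true(all(abs(a) <= 1))
  # bound holds for arbitrary weights too
  gen$params$g3.W <- gen$params$g3.W * 100
  expect_true(all(abs(forward_generator(gen, z)) <= 1))
  expect_error(forward_generator(gen, matrix(0, 1, 100)), "does not match")
})

test_that("noise draws are standard normal and seeded", {
  z1 <- draw_noise(2, 10000, rng_seed = 9)
  z2 <- draw_noise(2, 10000, rng_seed = 9)
  expect_identical(z1, z2)
  expect_identical(dim(z1), c(2L, 10000L))
  expect_lt(abs(mean(z1)), 0.05)
  expect_lt(abs(sd(z1) - 1), 0.05)
})
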