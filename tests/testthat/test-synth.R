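test_that("identical config, label and seed reproduce a recording bit-for-bit", {
  cfg <- quick_cfg()
  a <- generate_recording(cfg, label = 0, rng_seed = 7)
  b <- generate_recording(cfg, label = 0, rng_seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(attr(a, "events"), attr(b, "events"))
  d <- generate_recording(cfg, label = 0, rng_seed = 8)
  expect_false(identical(a$samples, d$samples))
  expect_length(a$samples, round(cfg$duration_s * 4000))
  expect_true(all(is.finite(a$samples)))
  expect_true(all(abs(a$samples) <= 1))
})

test_that("full-length recordings have the nominal 240,000 samples", {
  rec <- generate_recording(synth_config(), label = 1, rng_seed = 3)
  expect_length(rec$samples, 240000)
  expect_equal(rec$duration_s, 60)
  expect_equal(rec$sample_rate, 4000)
})

test_that("no noise and no bursts yield silence", {
  cfg <- synth_config(burst_rate_per_min = 0, noise_floor_rms = 0,
                      duration_s = 2)
  rec <- generate_recording(cfg, label = 0, rng_seed = 1)
  expect_true(all(rec$samples == 0))
})

test_that("pre-defecation class has more and stronger bursts (Monte Carlo)", {
  cfg <- quick_cfg(duration_s = 10)
  stats_for <- function(label) {
    res <- vapply(1:100, function(s) {
      r <- generate_recording(cfg, label, rng_seed = 1000 + s + label * 5000)
      # oracle: count events from the generator's internal event list
      c(n = nrow(attr(r, "events")), rms = sqrt(mean(r$samples^2)))
    }, numeric(2))
    rowMeans(res)
  }
  s0 <- stats_for(0)
  s1 <- stats_for(1)
  expect_gt(s1["n"], s0["n"])
  expect_gt(s1["rms"], s0["rms"])
})

test_that("a lone noise-free burst concentrates spectral energy in the configured band", {
  cfg <- synth_config(burst_rate_per_min = 30, noise_floor_rms = 0,
                      burst_duration_ms = c(150, 250), duration_s = 2)
  checked <- 0
  for (s in 1:15) {
    rec <- generate_recording(cfg, label = 0, rng_seed = 40 + s)
    ev <- attr(rec, "events")
    if (nrow(ev) != 1) next
    checked <- checked + 1
    mag <- Mod(stats::fft(rec$samples))
    n <- length(rec$samples)
    half <- mag[seq_len(n %/% 2)]
    f_peak <- (which.max(half) - 1) * 4000 / n
    bin_hz <- 4000 / n
    expect_gte(f_peak, cfg$burst_freq_band[1] - bin_hz)
    expect_lte(f_peak, cfg$burst_freq_band[2] + bin_hz)
    # the peak should sit near the drawn carrier; damping widens it a little
    expect_lt(abs(f_peak - ev$freq), 25)
  }
  expect_gte(checked, 3)
})

test_that("class-1 RMS is monotone in the amplitude multiplier", {
  mean_rms <- function(mult) {
    cfg <- synth_config(burst_amp_multiplier = mult, duration_s = 5)
    mean(vapply(1:50, function(s)
      sqrt(mean(generate_recording(cfg, 1, rng_seed = 600 + s)$samples^2)),
      numeric(1)))
  }
  rms <- vapply(c(1, 1.5, 3), mean_rms, numeric(1))
  expect_true(all(diff(rms) >= 0))
})

test_that("fixture sets have the requested composition", {
  cfg <- synth_config_separated(1000)
  fs <- generate_fixture_set(cfg, 200, 60, rng_seed = 1, window = 1000)
  expect_s3_class(fs, "frame_set")
  expect_equal(length(fs), 200)
  expect_equal(sum(fs$label == 1), 60)
  expect_equal(sum(fs$label == 0), 140)
  expect_equal(ncol(fs$values), 1000)
  expect_identical(fs$kind, "spectral")

  expect_equal(length(generate_fixture_set(cfg, 0, 0, rng_seed = 1,
                                           window = 1000)), 0)
  all_pos <- generate_fixture_set(cfg, 10, 10, rng_seed = 2, window = 1000)
  expect_true(all(all_pos$label == 1))
  expect_error(generate_fixture_set(cfg, 10, 11, rng_seed = 1),
               "n_positive")
})

test_that("fixture sets default to the 200-segment, 60-positive task at 10,000-sample windows", {
  expect_equal(formals(generate_fixture_set)$n_total, 200)
  expect_equal(formals(generate_fixture_set)$n_positive, 60)
  expect_equal(formals(generate_fixture_set)$window, 10000)
  small <- generate_fixture_set(synth_config(), 6, 2, rng_seed = 3)
  expect_equal(ncol(small$values), 10000)
  expect_equal(sum(small$label == 1), 2)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(synth_config(burst_freq_band = c(500, 100)), "degenerate")
  expect_error(synth_config(burst_freq_band = c(100, 2500)), "Nyquist")
  expect_error(synth_config(burst_rate_multiplier = 0.5), "multipliers")
  expect_error(synth_config(noise_floor_rms = -1), "noise_floor_rms")
  expect_error(generate_recording(quick_cfg(), label = 2, rng_seed = 1),
               "label")
})
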