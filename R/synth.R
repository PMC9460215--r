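#' Synthetic bowel-sound generator configuration
#'
#' Parameters of the statistical model the simulator draws recordings from.
#' A recording is a Gaussian noise floor plus a homogeneous Poisson process of
#' short acoustic bursts; each burst is an exponentially damped sinusoid whose
#' carrier frequency is drawn uniformly from `burst_freq_band`. The
#' pre-defecation class (label 1) differs from the baseline class (label 0)
#' only through the two multipliers: its burst rate is
#' `burst_rate_per_min * burst_rate_multiplier` and its mean peak amplitude
#' `burst_amp * burst_amp_multiplier`, reflecting the elevated rate and
#' amplitude of colonic motility before defecation.
#'
#' @param burst_rate_per_min Mean burst count per minute for class 0.
#' @param burst_rate_multiplier Class-1 rate relative to class 0 (>= 1).
#' @param burst_amp Mean peak amplitude of a class-0 burst (signal units,
#'   nominal full scale 1).
#' @param burst_amp_multiplier Class-1 amplitude relative to class 0 (>= 1).
#' @param burst_freq_band Length-2 numeric, Hz: carrier band, default
#'   100--500 Hz, the band where bowel-sound energy concentrates. Must lie
#'   below the Nyquist frequency (2000 Hz at the 4 kHz sampling rate).
#' @param burst_duration_ms Length-2 numeric: burst duration range,
#'   drawn uniformly, default 20--200 ms.
#' @param damping Exponential decay rate of the burst envelope, 1/s.
#' @param noise_floor_rms RMS of the additive Gaussian noise floor (>= 0).
#' @param sample_rate Sampling rate, Hz; fixed at 4000 for this instrument
#'   class.
#' @param duration_s Recording length in seconds, default 60 (240,000
#'   samples).
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(burst_rate_per_min = 30,
                         burst_rate_multiplier = 1.8,
                         burst_amp = 0.3,
                         burst_amp_multiplier = 1.5,
                         burst_freq_band = c(100, 500),
                         burst_duration_ms = c(20, 200),
                         damping = 40,
                         noise_floor_rms = 0.02,
                         sample_rate = 4000,
                         duration_s = 60) {
  stopifnot(length(burst_freq_band) == 2L, length(burst_duration_ms) == 2L)
  if (!(burst_freq_band[1] > 0 && burst_freq_band[1] < burst_freq_band[2]))
    stop("degenerate frequency band: need 0 < low < high", call. = FALSE)
  if (burst_freq_band[2] > sample_rate / 2)
    stop("frequency band exceeds the Nyquist frequency ", sample_rate / 2,
         " Hz", call. = FALSE)
  if (burst_rate_multiplier < 1 || burst_amp_multiplier < 1)
    stop("class-1 multipliers must be >= 1", call. = FALSE)
  if (noise_floor_rms < 0) stop("noise_floor_rms must be >= 0", call. = FALSE)
  if (burst_rate_per_min < 0) stop("burst_rate_per_min must be >= 0", call. = FALSE)
  stopifnot(duration_s > 0, sample_rate > 0)
  structure(list(
    burst_rate_per_min = burst_rate_per_min,
    burst_rate_multiplier = burst_rate_multiplier,
    burst_amp = burst_amp,
    burst_amp_multiplier = burst_amp_multiplier,
    burst_freq_band = as.numeric(burst_freq_band),
    burst_duration_ms = as.numeric(burst_duration_ms),
    damping = damping,
    noise_floor_rms = noise_floor_rms,
    sample_rate = sample_rate,
    duration_s = duration_s
  ), class = "synth_config")
}

#' Construct a bowel-sound recording object
#'
#' @param samples Numeric amplitude vector, nominally in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz (4000 for this instrument class).
#' @param label Class label: 0 (no defecation tendency), 1 (tendency), or
#'   `NA` for unlabeled.
#' @param subject_id Opaque subject/recording identifier.
#' @return An object of class `bs_recording`.
#' @export
bs_recording <- function(samples, sample_rate = 4000, label = NA,
                         subject_id = "synthetic") {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("samples must all be finite", call. = FALSE)
  if (!is.na(label) && !label %in% c(0, 1))
    stop("label must be 0, 1 or NA", call. = FALSE)
  structure(list(
    samples = samples,
    sample_rate = sample_rate,
    label = if (is.na(label)) NA_integer_ else as.integer(label),
    subject_id = subject_id,
    duration_s = length(samples) / sample_rate
  ), class = "bs_recording")
}

#' @export
print.bs_recording <- function(x, ...) {
  cat(sprintf("<bs_recording> %s: %d samples @ %d Hz (%.1f s), label %s\n",
              x$subject_id, length(x$samples), x$sample_rate, x$duration_s,
              ifelse(is.na(x$label), "unlabeled", x$label)))
  invisible(x)
}

#' Simulate one labeled bowel-sound recording
#'
#' Draws a recording from the generative model in [synth_config()]: burst
#' onset times from a homogeneous Poisson process (exponential gaps) with the
#' class-appropriate rate, each burst an exponentially damped sinusoid with a
#' carrier drawn from the configured band, plus Gaussian noise at
#' `noise_floor_rms`. The result is clipped to \[-1, 1\]. The injected event
#' list (onset time, carrier frequency, peak amplitude, duration) is attached
#' as attribute `"events"` so downstream checks can count ground-truth events
#' without re-deriving them from the waveform.
#'
#' @param config A [synth_config()].
#' @param label 0 (baseline) or 1 (pre-defecation).
#' @param rng_seed Integer seed; identical `(config, label, rng_seed)` give
#'   bit-identical samples.
#' @return A [bs_recording()] with attribute `"events"` (a data frame).
#' @examples
#' rec <- generate_recording(synth_config(duration_s = 5), label = 1, rng_seed = 7)
#' nrow(attr(rec, "events"))  # injected burst count
#' @export
generate_recording <- function(config, label, rng_seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (length(label) != 1L || !label %in% c(0, 1))
    stop("label must be 0 or 1", call. = FALSE)
  with_rng(rng_seed, {
    fs <- config$sample_rate
    n <- round(config$duration_s * fs)
    rate_per_s <- config$burst_rate_per_min / 60 *
      if (label == 1) config$burst_rate_multiplier else 1
    amp_mean <- config$burst_amp *
      if (label == 1) config$burst_amp_multiplier else 1

    x <- if (config$noise_floor_rms > 0)
      stats::rnorm(n, 0, config$noise_floor_rms) else numeric(n)

    # Poisson process via exponential inter-arrival gaps
    times <- numeric(0)
    if (rate_per_s > 0) {
      t <- stats::rexp(1, rate_per_s)
      while (t < config$duration_s) {
        times <- c(times, t)
        t <- t + stats::rexp(1, rate_per_s)
      }
    }
    events <- data.frame(time = numeric(0), freq = numeric(0),
                         amp = numeric(0), duration = numeric(0))
    for (t0 in times) {
      f <- stats::runif(1, config$burst_freq_band[1], config$burst_freq_band[2])
      d <- stats::runif(1, config$burst_duration_ms[1],
                        config$burst_duration_ms[2]) / 1000
      # lognormal spread around the class mean keeps amplitudes positive
      a <- amp_mean * stats::rlnorm(1, -0.125, 0.5)
      phase <- stats::runif(1, 0, 2 * pi)
      i0 <- floor(t0 * fs) + 1L
      i1 <- min(n, i0 + ceiling(d * fs) - 1L)
      if (i0 > n) next
      tt <- (seq.int(i0, i1) - i0) / fs
      x[i0:i1] <- x[i0:i1] +
        a * exp(-config$damping * tt) * sin(2 * pi * f * tt + phase)
      events <- rbind(events,
                      data.frame(time = t0, freq = f, amp = a, duration = d))
    }
    rec <- bs_recording(pmin(1, pmax(-1, x)), sample_rate = fs, label = label,
                        subject_id = sprintf("synth-%s-%s", label,
                                             ifelse(is.null(rng_seed), "live",
                                                    rng_seed)))
    attr(rec, "events") <- events
    rec
  })
}

#' Generate a labeled test-fixture segment set
#'
#' Builds a collection of preprocessed spectral frames mimicking the
#' composition of one evaluation task: `n_total` segments of which exactly
#' `n_positive` carry label 1. Defaults reproduce the 200-segment / 60-positive
#' task composition. Recordings are simulated per class, cut into
#' `window`-sample segments and FFT-transformed ([fft_transform()]).
#'
#' @param config A [synth_config()]; its `duration_s` is ignored (recordings
#'   are sized to the window).
#' @param n_total Total number of segments (default 200).
#' @param n_positive Number of label-1 segments (default 60).
#' @param rng_seed Integer seed.
#' @param window Segment length in samples (default 10,000 = 2.5 s at 4 kHz).
#' @param segments_per_recording How many windows each simulated recording
#'   contributes (default 4).
#' @return A [frame_set()] with `n_total` rows and labels 0/1.
#' @export
generate_fixture_set <- function(config, n_total = 200, n_positive = 60,
                                 rng_seed = NULL, window = 10000,
                                 segments_per_recording = 4) {
  stopifnot(inherits(config, "synth_config"))
  if (n_positive > n_total || n_positive < 0 || n_total < 0)
    stop("need 0 <= n_positive <= n_total", call. = FALSE)
  if (n_total == 0) return(empty_frame_set(window))
  with_rng(rng_seed, {
    gen_class <- function(lbl, n_seg) {
      if (n_seg == 0) return(NULL)
      cfg <- config
      cfg$duration_s <- window * segments_per_recording / config$sample_rate
      n_rec <- ceiling(n_seg / segments_per_recording)
      sets <- lapply(seq_len(n_rec), function(i) {
        rec <- generate_recording(cfg, lbl)
        rec$subject_id <- sprintf("fix-%d-%d", lbl, i)
        fft_transform(segment_recording(rec, window = window))
      })
      head_frames(do.call(rbind_frames, sets), n_seg)
    }
    neg <- gen_class(0L, n_total - n_positive)
    pos <- gen_class(1L, n_positive)
    out <- if (is.null(neg)) pos else if (is.null(pos)) neg else
      rbind_frames(neg, pos)
    out
  })
}
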