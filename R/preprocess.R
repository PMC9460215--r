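#' Segment / spectral-frame collections
#'
#' A `frame_set` holds fixed-length windows of recordings (or their spectral
#' transforms) as the rows of a numeric matrix, with per-row metadata: class
#' label (0, 1, or `NA` for unlabeled), source recording id and window index.
#' `kind` records whether rows are raw time-domain segments (`"segment"`) or
#' FFT-derived network inputs (`"spectral"`).
#'
#' @param values Numeric matrix, one row per frame.
#' @param label Integer vector of labels (0/1/`NA`), recycled if length 1.
#' @param recording_id Character vector of source ids.
#' @param window_index Integer vector of 0-based window positions.
#' @param kind `"segment"` or `"spectral"`.
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(values, label = NA_integer_, recording_id = "unknown",
                      window_index = 0L, kind = c("segment", "spectral")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  n <- nrow(values)
  structure(list(
    values = values,
    label = rep_len(as.integer(label), n),
    recording_id = rep_len(as.character(recording_id), n),
    window_index = rep_len(as.integer(window_index), n),
    kind = kind
  ), class = "frame_set")
}

empty_frame_set <- function(width, kind = "spectral") {
  frame_set(matrix(numeric(0), nrow = 0, ncol = width), integer(0),
            character(0), integer(0), kind = kind)
}

#' @export
print.frame_set <- function(x, ...) {
  nl <- sum(!is.na(x$label))
  cat(sprintf("<frame_set> %d %s frames x %d values; %d labeled (%d positive)\n",
              nrow(x$values), x$kind, ncol(x$values), nl,
              sum(x$label == 1L, na.rm = TRUE)))
  invisible(x)
}

#' @export
length.frame_set <- function(x) nrow(x$values)

#' Combine or subset frame sets
#' @param ... `frame_set` objects of matching width and kind.
#' @return A single `frame_set`.
#' @export
rbind_frames <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "frame_set")))
  kinds <- unique(vapply(sets, `[[`, character(1), "kind"))
  if (length(kinds) != 1L) stop("cannot combine segment and spectral frames",
                                call. = FALSE)
  frame_set(do.call(rbind, lapply(sets, `[[`, "values")),
            unlist(lapply(sets, `[[`, "label")),
            unlist(lapply(sets, `[[`, "recording_id")),
            unlist(lapply(sets, `[[`, "window_index")),
            kind = kinds)
}

#' @rdname rbind_frames
#' @param x A `frame_set`.
#' @param i Row indices.
#' @export
subset_frames <- function(x, i) {
  frame_set(x$values[i, , drop = FALSE], x$label[i], x$recording_id[i],
            x$window_index[i], kind = x$kind)
}

head_frames <- function(x, n) subset_frames(x, seq_len(min(n, length(x))))

#' Cut a recording into non-overlapping fixed-length segments
#'
#' Splits the amplitude series into `floor(length / window)` consecutive
#' windows in temporal order; a trailing remainder shorter than `window` is
#' discarded. Every segment inherits the recording's label. The nominal
#' 60-second recording (240,000 samples at 4 kHz) yields 24 windows of
#' 10,000 samples (2.5 s each), the unit of classification.
#'
#' @param recording A [bs_recording()].
#' @param window Window length in samples (default 10,000).
#' @return A `frame_set` of kind `"segment"` (possibly with 0 rows).
#' @export
segment_recording <- function(recording, window = 10000) {
  stopifnot(inherits(recording, "bs_recording"))
  if (window <= 0) stop("window must be positive", call. = FALSE)
  n <- length(recording$samples)
  if (n == 0) stop("empty recording", call. = FALSE)
  k <- n %/% window
  if (k == 0) return(empty_frame_set(window, kind = "segment"))
  vals <- matrix(recording$samples[seq_len(k * window)],
                 nrow = k, ncol = window, byrow = TRUE)
  frame_set(vals, label = recording$label, recording_id = recording$subject_id,
            window_index = seq_len(k) - 1L, kind = "segment")
}

#' Transform time-domain segments into normalized spectral frames
#'
#' Computes the full two-sided discrete Fourier transform magnitude of each
#' segment (same length as the input, mirror half retained so the network
#' input shape matches the time-domain shape), compresses it with `log1p`,
#' and min-max rescales each frame to \[-1, 1\]. The \[-1, 1\] range matches
#' the generator's Tanh output so real and generated inputs share a common
#' scale. A degenerate frame (max == min, e.g. all-zero input) maps to the
#' constant -1.
#'
#' @param segments A `frame_set` of kind `"segment"`, or a single numeric
#'   vector.
#' @return A `frame_set` of kind `"spectral"` with values in \[-1, 1\].
#' @export
fft_transform <- function(segments) {
  if (is.numeric(segments) && is.null(dim(segments)))
    segments <- frame_set(matrix(segments, nrow = 1), kind = "segment")
  stopifnot(inherits(segments, "frame_set"))
  if (!all(is.finite(segments$values)))
    stop("non-finite values in input segments", call. = FALSE)
  v <- segments$values
  out <- if (nrow(v) == 0) v else {
    # mvfft works on columns
    mag <- abs(t(stats::mvfft(t(v))))
    lg <- log1p(mag)
    lo <- apply(lg, 1, min)
    hi <- apply(lg, 1, max)
    span <- hi - lo
    span[span == 0] <- 1           # degenerate frames -> all -1
    2 * (lg - lo) / span - 1
  }
  frame_set(out, segments$label, segments$recording_id, segments$window_index,
            kind = "spectral")
}

#' Split recordings into labeled, unlabeled and test frame pools
#'
#' Splits at the *recording* level so no recording contributes frames to both
#' a training pool and the test pool, then segments and FFT-transforms each
#' group. Within the training recordings, a fraction `labeled_fraction` keep
#' their labels; the rest have labels stripped and form the unlabeled pool
#' that feeds the unsupervised loss term. Test frames keep labels for
#' evaluation.
#'
#' @param recordings List of labeled [bs_recording()] objects (both classes
#'   present, at least 2 recordings per class).
#' @param labeled_fraction Fraction of training recordings that stay labeled
#'   (0 < f <= 1).
#' @param rng_seed Integer seed; the split is deterministic under it.
#' @param test_fraction Fraction of recordings (per class) held out for
#'   testing, default 0.25.
#' @param window Segment length, default 10,000.
#' @return A list with `frame_set` elements `labeled`, `unlabeled`, `test`.
#' @export
build_dataset <- function(recordings, labeled_fraction = 1, rng_seed = NULL,
                          test_fraction = 0.25, window = 10000) {
  stopifnot(is.list(recordings))
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    stop("labeled_fraction must be in (0, 1]", call. = FALSE)
  labs <- vapply(recordings, `[[`, integer(1), "label")
  if (any(is.na(labs))) stop("all recordings must carry labels", call. = FALSE)
  if (any(table(factor(labs, levels = 0:1)) < 2))
    stop("need at least 2 recordings per class", call. = FALSE)

  with_rng(rng_seed, {
    test_idx <- integer(0); train_idx <- integer(0)
    for (cl in 0:1) {
      idx <- sample(which(labs == cl))
      n_test <- max(1L, round(test_fraction * length(idx)))
      test_idx <- c(test_idx, idx[seq_len(n_test)])
      train_idx <- c(train_idx, idx[-seq_len(n_test)])
    }
    n_lab <- max(1L, round(labeled_fraction * length(train_idx)))
    lab_idx <- sort(sample(train_idx, n_lab))
    unlab_idx <- setdiff(train_idx, lab_idx)

    to_frames <- function(idx, strip = FALSE) {
      if (length(idx) == 0) return(empty_frame_set(window))
      sets <- lapply(recordings[idx], function(r)
        fft_transform(segment_recording(r, window = window)))
      out <- do.call(rbind_frames, sets)
      if (strip) out$label <- rep(NA_integer_, length(out))
      out
    }
    list(labeled = to_frames(lab_idx),
         unlabeled = to_frames(unlab_idx, strip = TRUE),
         test = to_frames(sort(test_idx)))
  })
}
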