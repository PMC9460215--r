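#' Write a recording to a 16-bit PCM mono WAV file
#'
#' Emits the plain RIFF/WAVE dialect electronic-stethoscope exports use:
#' PCM, one channel, 16 bits per sample. Amplitudes are clipped to \[-1, 1\]
#' and quantized to the signed 16-bit grid, so a round trip preserves sample
#' count and rate exactly and amplitudes to within 2^-15.
#'
#' @param recording A [bs_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path) {
  stopifnot(inherits(recording, "bs_recording"))
  x <- pmin(1, pmax(-1, recording$samples))
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(recording$sample_rate)
  n <- length(pcm)
  data_bytes <- 2L * n

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")        # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")         # PCM
  writeBin(1L, con, size = 2, endian = "little")         # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")    # byte rate
  writeBin(2L, con, size = 2, endian = "little")         # block align
  writeBin(16L, con, size = 2, endian = "little")        # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file as a recording
#'
#' Parses RIFF chunks, requiring PCM encoding and a single channel. Files at
#' a sampling rate other than 4000 Hz are either rejected or resampled to
#' 4000 Hz (via `signal::resample`) depending on `off_rate`.
#'
#' @param path WAV file path.
#' @param label Optional class label to attach (0, 1, or `NA`).
#' @param off_rate What to do when the file's rate is not 4000 Hz:
#'   `"error"` (default) or `"resample"` (warns, then resamples).
#' @return A [bs_recording()].
#' @export
read_wav <- function(path, label = NA, off_rate = c("error", "resample")) {
  off_rate <- match.arg(off_rate)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file", call. = FALSE)

  fmt <- NULL; pcm <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      audio_format <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_channels <- readBin(con, "integer", 1, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      fmt <- list(format = audio_format, channels = n_channels,
                  rate = sample_rate, bits = bits)
      if (sz > 16) readBin(con, "raw", sz - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      pcm <- readBin(con, "integer", sz / 2L, size = 2, signed = TRUE,
                     endian = "little")
      break
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
  }
  if (is.null(fmt) || is.null(pcm)) stop("malformed WAV file", call. = FALSE)
  if (fmt$format != 1L) stop("only PCM WAV is supported", call. = FALSE)
  if (fmt$bits != 16L) stop("only 16-bit WAV is supported", call. = FALSE)
  if (fmt$channels != 1L)
    stop("only mono WAV is supported (file has ", fmt$channels, " channels)",
         call. = FALSE)

  x <- pcm / 32767
  rate <- fmt$rate
  if (rate != 4000L) {
    if (off_rate == "error")
      stop("sample rate is ", rate, " Hz, expected 4000 (use off_rate = ",
           '"resample")', call. = FALSE)
    warning("resampling from ", rate, " Hz to 4000 Hz")
    g <- gcd_int(4000L, rate)
    x <- signal::resample(x, 4000L / g, rate / g)
    rate <- 4000L
  }
  bs_recording(x, sample_rate = rate, label = label,
               subject_id = basename(path))
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)
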