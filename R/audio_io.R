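#' Recording objects
#'
#' A `Recording` is the unit of analysis throughout pvq: a mono waveform with
#' its sample rate and an opaque source label. Samples are dimensionless
#' amplitudes in \[-1, 1\].
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param rate Sample rate in Hz (> 0).
#' @param source_id Opaque label identifying the recording.
#' @return An object of class `Recording`.
#' @export
recording <- function(samples, rate, source_id = "unnamed") {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  if (length(samples) && !all(is.finite(samples)))
    stop("samples must be finite", call. = FALSE)
  structure(
    list(samples = samples, rate = as.numeric(rate),
         source_id = as.character(source_id)),
    class = "Recording")
}

#' @export
print.Recording <- function(x, ...) {
  cat(sprintf("<Recording '%s': %d samples @ %g Hz (%.3f s)>\n",
              x$source_id, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.Recording <- function(x) length(x$samples)

duration_s <- function(rec) length(rec$samples) / rec$rate

stopifnot_recording <- function(rec, min_dur = NULL) {
  if (!inherits(rec, "Recording")) stop("expected a Recording", call. = FALSE)
  if (!is.null(min_dur) && duration_s(rec) < min_dur)
    stop(sprintf("Recording '%s' is %.3f s; at least %.2f s required",
                 rec$source_id, duration_s(rec), min_dur), call. = FALSE)
  invisible(rec)
}

#' Read a PCM WAV file
#'
#' Reads a 16-bit (or 8/24/32-bit integer, or 32/64-bit float) PCM RIFF WAV
#' file. Multichannel files are reduced to channel 1 with a warning. Integer
#' samples are scaled to \[-1, 1\] by the full-scale value (32768 for 16-bit).
#'
#' @param path Path to a WAV file.
#' @param source_id Label for the returned [recording()]; defaults to the
#'   file name without extension.
#' @return A `Recording` at the file's native rate.
#' @export
read_wav <- function(path, source_id = NULL) {
  if (!file.exists(path) || file.info(path)$size == 0)
    stop(sprintf("cannot read WAV file '%s' (missing or empty)", path),
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop(sprintf("'%s' is not a RIFF/WAV file", path), call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop(sprintf("'%s' is not a WAVE file", path), call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        rate         = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little",
                               signed = FALSE))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      break
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0)
    stop(sprintf("'%s' has no usable fmt/data chunks", path), call. = FALSE)

  bytes <- fmt$bits %/% 8
  n_total <- length(data_raw) %/% (bytes * fmt$n_channels)
  if (n_total == 0) stop(sprintf("'%s' contains no samples", path),
                         call. = FALSE)
  if (fmt$audio_format == 3L || fmt$bits >= 32 && fmt$audio_format != 1L) {
    x <- readBin(data_raw, "double", n_total * fmt$n_channels, size = bytes,
                 endian = "little")
  } else if (fmt$bits == 8) {
    x <- (readBin(data_raw, "integer", n_total * fmt$n_channels, size = 1,
                  signed = FALSE, endian = "little") - 128) / 128
  } else if (fmt$bits == 24) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    x <- v / 8388608
  } else {
    x <- readBin(data_raw, "integer", n_total * fmt$n_channels, size = bytes,
                 signed = TRUE, endian = "little") / 2^(fmt$bits - 1)
  }
  if (fmt$n_channels > 1) {
    warning(sprintf("'%s' has %d channels; using channel 1", path,
                    fmt$n_channels))
    x <- x[seq(1, length(x), by = fmt$n_channels)]
  }
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  recording(x, fmt$rate, source_id)
}

#' Write a Recording to a 16-bit PCM WAV file
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot_recording(rec)
  x <- pmax(pmin(rec$samples, 1 - 2^-15), -1)
  pcm <- as.integer(round(x * 32768))
  pcm <- pmax(pmin(pcm, 32767L), -32768L)
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rec$rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Band-limited resampling to 16 kHz
#'
#' Decimates a recording to a 16 kHz rate with an ideal (frequency-domain)
#' anti-alias lowpass at 0.45 x 16 kHz = 7.2 kHz, so passband content below
#' 7 kHz is preserved essentially exactly. The input is trimmed by at most
#' `fs / gcd(fs, 16000) - 1` samples (10 ms at 44.1 kHz) so the rational rate
#' ratio maps whole samples to whole samples.
#'
#' @param rec A [recording()] with `rate >= 16000`.
#' @return A `Recording` at exactly 16000 Hz.
#' @export
decimate_to_16k <- function(rec) {
  stopifnot_recording(rec)
  fs <- rec$rate
  if (fs < 16000) stop("cannot upsample: input rate below 16 kHz",
                       call. = FALSE)
  if (fs == 16000) return(rec)
  recording(fft_resample(rec$samples, fs, 16000), 16000, rec$source_id)
}

rational_gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# Exact FFT-domain band-limited resampling fs_in -> fs_out with an ideal
# lowpass at cutoff_frac * fs_out. The input is trimmed to a whole number of
# fs_in/gcd(fs_in, fs_out) blocks so the rational ratio maps whole input
# lengths to whole output lengths.
fft_resample <- function(x, fs_in, fs_out, cutoff_frac = 0.45) {
  g <- rational_gcd(round(fs_in), round(fs_out))
  block <- round(fs_in) / g
  N <- (length(x) %/% block) * block
  if (N < block) stop("signal too short to resample", call. = FALSE)
  x <- x[seq_len(N)]
  M <- N * round(fs_out) / round(fs_in)
  X <- stats::fft(x)
  cutoff <- cutoff_frac * fs_out
  kmax <- floor(M / 2)
  Y <- complex(real = numeric(M), imaginary = numeric(M))
  k <- 0:(kmax - 1)
  keep <- k[k * fs_in / N <= cutoff]
  Y[keep + 1] <- X[keep + 1]
  pos <- keep[keep > 0]
  Y[M - pos + 1] <- X[N - pos + 1]
  Re(stats::fft(Y, inverse = TRUE)) / N * (1)
}

#' Extract the central segment of a recording
#'
#' Returns the `duration_s`-second block centred on the midpoint of the
#' recording (start index `floor((N - L) / 2)`, biasing one sample left for
#' odd remainders).
#'
#' @param rec A [recording()].
#' @param duration_s Segment duration in seconds (default 2).
#' @return A `Recording` of `round(duration_s * rate)` samples.
#' @export
extract_central_segment <- function(rec, duration_s = 2.0) {
  stopifnot_recording(rec)
  L <- round(duration_s * rec$rate)
  N <- length(rec$samples)
  if (N < L)
    stop(sprintf("recording '%s' (%.3f s) is shorter than %.3f s",
                 rec$source_id, N / rec$rate, duration_s), call. = FALSE)
  start <- floor((N - L) / 2)
  recording(rec$samples[(start + 1):(start + L)], rec$rate, rec$source_id)
}

#' Split a recording into fixed-length windowed frames
#'
#' Frames are laid out every `hop` samples; a trailing partial frame is
#' discarded, giving `floor((N - frame_len) / hop) + 1` frames. Each frame is
#' multiplied elementwise by the named window.
#'
#' @param rec A [recording()].
#' @param frame_len Frame length in samples.
#' @param hop Hop (frame advance) in samples, >= 1.
#' @param window_name One of `"hamming"`, `"hanning"`, `"rectangular"`.
#' @return A `FrameSequence`: list with `frames` (a `frame_len` x `n_frames`
#'   matrix), `frame_len`, `hop`, `window_name`, `rate`.
#' @export
frame_signal <- function(rec, frame_len, hop, window_name = "hamming") {
  stopifnot_recording(rec)
  N <- length(rec$samples)
  frame_len <- as.integer(frame_len); hop <- as.integer(hop)
  if (hop < 1L) stop("hop must be >= 1", call. = FALSE)
  if (frame_len > N)
    stop("frame_len exceeds recording length", call. = FALSE)
  n_frames <- (N - frame_len) %/% hop + 1L
  w <- switch(window_name,
    hamming = signal::hamming(frame_len),
    hanning = signal::hanning(frame_len),
    rectangular = rep(1, frame_len),
    stop(sprintf("unknown window '%s'", window_name), call. = FALSE))
  idx <- outer(seq_len(frame_len), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(rec$samples[idx], nrow = frame_len) * w
  structure(
    list(frames = frames, frame_len = frame_len, hop = hop,
         window_name = window_name, rate = rec$rate),
    class = "FrameSequence")
}

#' @export
print.FrameSequence <- function(x, ...) {
  cat(sprintf("<FrameSequence: %d frames of %d samples, hop %d, %s window>\n",
              ncol(x$frames), x$frame_len, x$hop, x$window_name))
  invisible(x)
}
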