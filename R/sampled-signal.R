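#' Uniformly sampled time series
#'
#' The basic carrier for speech envelopes and neural channel recordings: a
#' numeric vector with a sampling rate and a start time.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds (default 0).
#' @return An object of class `sampled_signal` with elements `x`, `fs`, `t0`.
#' @examples
#' s <- sampled_signal(sin(2 * pi * 5 * seq(0, 1, by = 1/200)), fs = 200)
#' signal_duration(s)
#' @export
sampled_signal <- function(x, fs, t0 = 0) {
  if (!is.numeric(x) || length(x) < 1L) stop("x must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  structure(list(x = as.numeric(x), fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %.6g Hz (%.3f s)\n",
              length(x$x), x$fs, signal_duration(x)))
  invisible(x)
}

#' Duration of a sampled signal in seconds
#' @param s a `sampled_signal`.
#' @return duration in seconds (n / fs).
#' @export
signal_duration <- function(s) length(s$x) / s$fs

#' Time axis of a sampled signal
#' @param s a `sampled_signal`.
#' @return numeric vector of sample times in seconds.
#' @export
signal_times <- function(s) s$t0 + (seq_along(s$x) - 1) / s$fs

as_sampled_signal <- function(x, fs) {
  if (inherits(x, "sampled_signal")) x else sampled_signal(x, fs)
}

#' Read a single-column signal file
#'
#' Reads the plain-text exchange format used throughout the package: one
#' sample per row, preceded by a comment header line `# fs=<Hz>`.
#'
#' @param path file path.
#' @return a [sampled_signal()].
#' @export
read_signal_csv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#\\s*fs\\s*=\\s*([0-9.eE+-]+)", header))[[1]]
  if (length(m) < 2L) stop("missing '# fs=<Hz>' header in ", path)
  fs <- as.numeric(m[2])
  x <- utils::read.csv(path, header = FALSE, comment.char = "#")[[1]]
  sampled_signal(x, fs)
}

#' Write a single-column signal file
#'
#' @param s a [sampled_signal()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", s$fs), con)
  writeLines(format(s$x, digits = 15, scientific = TRUE, trim = TRUE), con)
  invisible(path)
}

#' Read a RIFF/WAVE audio file as a mono sampled signal
#'
#' Minimal PCM WAV reader (16/24/32-bit integer and 32/64-bit float).
#' Multi-channel audio is converted to mono by channel averaging, matching a
#' binaurally identical stimulus presentation.
#'
#' @param path path to a .wav file.
#' @return a [sampled_signal()] with samples scaled to [-1, 1] for integer PCM.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_channels   = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(raw[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk)")
  bits <- fmt$bits
  if (fmt$audio_format == 1L) {  # integer PCM
    if (bits == 16L) {
      x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                   signed = TRUE, endian = "little") / 32768
    } else if (bits == 24L) {
      b <- as.integer(data_raw)
      n <- length(b) %/% 3
      v <- b[seq(1, 3 * n, 3)] + 256 * b[seq(2, 3 * n, 3)] + 65536 * b[seq(3, 3 * n, 3)]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      x <- v / 8388608
    } else if (bits == 32L) {
      x <- readBin(data_raw, "integer", length(data_raw) / 4, size = 4,
                   endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", bits)
  } else if (fmt$audio_format == 3L) {  # IEEE float
    x <- readBin(data_raw, "double", length(data_raw) / (bits / 8),
                 size = bits / 8, endian = "little")
  } else stop("unsupported WAV audio format code: ", fmt$audio_format)
  if (fmt$n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  sampled_signal(x, fmt$sample_rate)
}
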