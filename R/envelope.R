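#' Greenwood cochlear position-frequency map (human)
#'
#' `greenwood(x)` maps normalised basilar-membrane position `x` in [0, 1]
#' (apex to base) to characteristic frequency in Hz, using the human
#' parameters f(x) = A (10^(a x) - k) with A = 165.4, a = 2.1, k = 0.88.
#' `greenwood_position(f)` is the inverse.
#'
#' @param x position(s) in [0, 1].
#' @param f frequency or frequencies in Hz.
#' @return frequencies in Hz, or positions in [0, 1].
#' @export
greenwood <- function(x) 165.4 * (10^(2.1 * x) - 0.88)

#' @rdname greenwood
#' @export
greenwood_position <- function(f) log10(f / 165.4 + 0.88) / 2.1

#' Cochlear-spaced frequency band edges
#'
#' Band edges for a filterbank whose bands are equidistant on the cochlear
#' map: the images under the Greenwood map of equally spaced cochlear
#' positions between the positions of `lo` and `hi`.
#'
#' @param n_bands number of contiguous bands (default 9).
#' @param lo,hi outer edges in Hz (defaults 100 and 10000).
#' @return an object of class `cochlear_bands` with `edges` (length
#'   `n_bands + 1`, strictly increasing, endpoints exactly `lo` and `hi`) and
#'   `bands` (a `n_bands` x 2 matrix of lo/hi pairs). The Greenwood
#'   parameters used are attached as the `map_params` attribute.
#' @examples
#' cochlear_band_edges()$edges
#' @export
cochlear_band_edges <- function(n_bands = 9, lo = 100, hi = 10000) {
  if (lo <= 0) stop("lo must be positive")
  if (hi <= lo) stop("hi must exceed lo")
  if (n_bands < 1) stop("need at least one band")
  if (greenwood_position(hi) > 1)
    stop("hi above the Greenwood map domain (", round(greenwood(1)), " Hz)")
  xs <- seq(greenwood_position(lo), greenwood_position(hi),
            length.out = n_bands + 1)
  edges <- greenwood(xs)
  edges[1] <- lo
  edges[n_bands + 1] <- hi
  structure(list(edges = edges,
                 bands = cbind(lo = edges[-(n_bands + 1)], hi = edges[-1])),
            class = "cochlear_bands",
            map_params = c(A = 165.4, a = 2.1, k = 0.88))
}

#' @export
print.cochlear_bands <- function(x, ...) {
  cat("<cochlear_bands>", nrow(x$bands), "bands, edges (Hz):",
      paste(signif(x$edges, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Wideband amplitude envelope of a speech waveform
#'
#' Band-pass filters the audio in cochlear-spaced bands (4th-order
#' Butterworth, forward and reverse), takes the magnitude of the Hilbert
#' analytic signal in each band, and averages the per-band envelopes.
#'
#' @param audio a [sampled_signal()] (use [read_wav()] for WAV input).
#' @param bands a [cochlear_band_edges()] result (default: 9 bands,
#'   100-10000 Hz).
#' @return a [sampled_signal()]: the non-negative wideband envelope, same
#'   length and sampling rate as the input.
#' @export
wideband_envelope <- function(audio, bands = cochlear_band_edges()) {
  if (!inherits(audio, "sampled_signal")) stop("audio must be a sampled_signal")
  hi <- max(bands$edges)
  if (audio$fs <= 2 * hi)
    stop(sprintf("audio fs = %g Hz too low for the %g Hz band edge (aliasing)",
                 audio$fs, hi))
  if (length(audio$x) < 64L) stop("audio shorter than the filter warm-up")
  acc <- numeric(length(audio$x))
  for (i in seq_len(nrow(bands$bands))) {
    bl <- band_limit_core(audio$x, bands$bands[i, 1], bands$bands[i, 2], audio$fs)
    acc <- acc + Mod(analytic_series(bl))
  }
  sampled_signal(acc / nrow(bands$bands), audio$fs, audio$t0)
}

#' Resample an envelope to a lower sampling rate
#'
#' Applies a zero-phase Butterworth anti-alias low-pass at 0.4 x the target
#' rate, then interpolates linearly onto the target time grid. Upsampling
#' beyond the source rate is refused: envelopes are only ever brought down to
#' the neural channel rate.
#'
#' @param env a [sampled_signal()].
#' @param target_fs target sampling rate in Hz (> 20).
#' @return a [sampled_signal()] at `target_fs`, duration preserved within one
#'   sample.
#' @export
resample_envelope <- function(env, target_fs) {
  if (!inherits(env, "sampled_signal")) stop("env must be a sampled_signal")
  if (target_fs <= 20) stop("target_fs must exceed 20 Hz")
  if (target_fs > env$fs) stop("refusing to upsample beyond the source rate")
  if (target_fs == env$fs) return(env)
  y <- band_limit_core(env$x, 0, 0.4 * target_fs, env$fs)
  t_src <- (seq_along(y) - 1) / env$fs
  n_out <- floor(signal_duration(env) * target_fs)
  t_out <- (seq_len(n_out) - 1) / target_fs
  sampled_signal(stats::approx(t_src, y, xout = t_out, rule = 2)$y,
                 target_fs, env$t0)
}
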