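#' Frequency band specification
#'
#' A band is stored by its literal edges. [band_spec()] builds one from a
#' centre frequency and half-width; [band_range()] from explicit edges, which
#' is how the canonical delta (1-3 Hz), theta (3-7 Hz) and gamma (35-45 Hz)
#' bands are defined.
#'
#' @param center centre frequency in Hz.
#' @param half_width half-width in Hz; the band is `center +/- half_width`.
#' @return an object of class `band_spec` with elements `lo`, `hi`, `center`,
#'   `half_width`.
#' @export
band_spec <- function(center, half_width) {
  if (half_width <= 0) stop("half_width must be positive")
  structure(list(lo = center - half_width, hi = center + half_width,
                 center = center, half_width = half_width),
            class = "band_spec")
}

#' @rdname band_spec
#' @param lo,hi band edges in Hz (`lo < hi`; `lo <= 0` denotes a low-pass band).
#' @export
band_range <- function(lo, hi) {
  if (hi <= lo) stop("hi must exceed lo")
  structure(list(lo = lo, hi = hi, center = (lo + hi) / 2,
                 half_width = (hi - lo) / 2),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %.6g-%.6g Hz\n", x$lo, x$hi)); invisible(x)
}

#' Default analysis band around a centre frequency
#'
#' Frequency scans band-limit at each centre frequency with a fixed
#' half-width: +/-1 Hz up to 40 Hz, +/-5 Hz above 40 Hz. The boundary centre
#' 40 Hz is assigned to the narrow rule.
#'
#' @param center centre frequency in Hz, at least 1.
#' @return a [band_spec()].
#' @examples
#' default_band(10)  # 9-11 Hz
#' default_band(45)  # 40-50 Hz
#' @export
default_band <- function(center) {
  if (!is.numeric(center) || length(center) != 1L || center < 1)
    stop("center must be a single frequency >= 1 Hz")
  band_spec(center, half_width = if (center <= 40) 1 else 5)
}

#' Canonical oscillation bands
#'
#' Named frequency ranges for the prosodic, syllabic and phonemic time scales:
#' delta 1-3 Hz, theta 3-7 Hz, gamma 35-45 Hz.
#'
#' @param name one of `"delta"`, `"theta"`, `"gamma"`.
#' @return a [band_spec()].
#' @export
canonical_band <- function(name) {
  switch(match.arg(name, c("delta", "theta", "gamma")),
         delta = band_range(1, 3),
         theta = band_range(3, 7),
         gamma = band_range(35, 45))
}

# ---------------------------------------------------------------------------
# Zero-phase Butterworth filtering.
#
# The 4th-order Butterworth band-pass applied forward and reverse is realised
# as a cascade of second-order sections derived from the zero-pole-gain
# design (analog prototype -> band transform -> bilinear transform). The
# transfer-function (b, a) form is numerically unusable for narrow bands at
# ~1 kHz sampling rates (pole clustering), while biquads remain stable.
# ---------------------------------------------------------------------------

butter_proto_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Design n-th order Butterworth as second-order sections.
# lo <= 0 requests a low-pass at hi. Returns list(b = k x 3, a = k x 3).
design_butter_sos <- function(n, lo, hi, fs) {
  if (hi >= fs / 2) stop("band edge ", hi, " Hz at or above Nyquist (fs = ", fs, " Hz)")
  if (hi <= max(lo, 0)) stop("invalid band edges")
  fs2 <- 2 * fs
  p <- butter_proto_poles(n)
  if (lo <= 0) {
    wc <- fs2 * tan(pi * hi / fs)
    ps <- wc * p
    zs <- complex(0)
    ks <- wc^n
  } else {
    w1 <- fs2 * tan(pi * lo / fs)
    w2 <- fs2 * tan(pi * hi / fs)
    bw <- w2 - w1
    w0 <- sqrt(w1 * w2)
    plp <- p * bw / 2
    rt <- sqrt(plp^2 - w0^2)
    ps <- c(plp + rt, plp - rt)
    zs <- rep(0 + 0i, n)
    ks <- bw^n
  }
  # bilinear transform of zeros, poles, gain
  pz <- (fs2 + ps) / (fs2 - ps)
  kz <- ks * Re(prod(fs2 - zs) / prod(fs2 - ps))
  zz <- c((fs2 + zs) / (fs2 - zs), rep(-1 + 0i, length(ps) - length(zs)))

  # group poles into conjugate-pair biquads
  tol <- 1e-9
  pc <- pz[Im(pz) > tol]
  pr <- sort(Re(pz[abs(Im(pz)) <= tol]))
  dens <- lapply(pc, function(pp) c(1, -2 * Re(pp), Mod(pp)^2))
  if (length(pr) %% 2L == 1L) stop("internal: odd count of real poles")
  if (length(pr) > 0) {
    for (i in seq(1, length(pr), by = 2)) {
      dens[[length(dens) + 1L]] <- c(1, -(pr[i] + pr[i + 1]), pr[i] * pr[i + 1])
    }
  }
  nsec <- length(dens)
  # all zeros in these designs are real (+1 / -1); hand each section one from
  # each pool while both last, so band-pass sections get zeros at +/-1
  zneg <- sum(Re(zz) < 0)
  zpos <- length(zz) - zneg
  nums <- vector("list", nsec)
  for (i in seq_len(nsec)) {
    pair <- c()
    for (j in 1:2) {
      if (zpos >= zneg && zpos > 0) { pair <- c(pair, 1); zpos <- zpos - 1 }
      else if (zneg > 0) { pair <- c(pair, -1); zneg <- zneg - 1 }
      else pair <- c(pair, NA)
    }
    if (anyNA(pair)) stop("internal: zero/pole count mismatch")
    nums[[i]] <- c(1, -(pair[1] + pair[2]), pair[1] * pair[2])
  }
  g1 <- kz^(1 / nsec)  # kz > 0 for these designs
  b <- do.call(rbind, lapply(nums, function(v) v * g1))
  a <- do.call(rbind, dens)
  list(b = b, a = a)
}

sosfilt <- function(sos, x) {
  for (i in seq_len(nrow(sos$b))) {
    x <- as.numeric(signal::filter(sos$b[i, ], sos$a[i, ], x))
  }
  x
}

# zero-phase filtering with odd-reflection padding
sos_filtfilt <- function(sos, x, padlen) {
  nx <- length(x)
  padlen <- min(padlen, nx - 1L)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
    post <- 2 * x[nx] - x[seq(nx - 1L, nx - padlen)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- sosfilt(sos, xp)
  y <- rev(sosfilt(sos, rev(y)))
  if (padlen > 0) y[(padlen + 1L):(padlen + nx)] else y
}

band_limit_core <- function(x, lo, hi, fs, order = 4) {
  # settle length scales with both the lower edge and the bandwidth: narrow
  # low-frequency bands ring for seconds
  f_ref <- if (lo > 0) min(lo, hi - lo) else hi
  padlen <- as.integer(min(length(x) - 1L, ceiling(6 * fs / max(f_ref, 0.25))))
  sos <- design_butter_sos(order, lo, hi, fs)
  sos_filtfilt(sos, x, padlen)
}

#' Band-limit a signal with a zero-phase Butterworth filter
#'
#' Applies a 4th-order Butterworth filter forward and reverse (zero phase
#' shift, 8th-order magnitude response) restricted to the given band. A band
#' whose lower edge is at or below 0 Hz (e.g. the 1 Hz scan band 0-2 Hz) is
#' realised as a low-pass at the upper edge.
#'
#' @param x a [sampled_signal()] (or numeric vector with `fs` supplied).
#' @param band a [band_spec()].
#' @param fs sampling rate, required when `x` is a bare numeric vector.
#' @param order filter order before the forward-reverse pass (default 4).
#' @return a [sampled_signal()] with the band-limited samples.
#' @export
band_limit <- function(x, band, fs = NULL, order = 4) {
  s <- if (inherits(x, "sampled_signal")) x else sampled_signal(x, fs)
  if (s$fs <= 2 * band$hi)
    stop(sprintf("fs = %g Hz cannot represent the %g-%g Hz band (aliasing)",
                 s$fs, band$lo, band$hi))
  if (length(s$x) < 12L) stop("signal too short to filter")
  sampled_signal(band_limit_core(s$x, band$lo, band$hi, s$fs, order), s$fs, s$t0)
}

# smallest 5-smooth (2^a 3^b 5^c) integer >= n; mixed-radix FFT lengths with
# large prime factors degrade to O(n^2)
next_fast_len <- function(n) {
  if (n <= 6) return(n)
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k %/% p
    if (k == 1) return(m)
    m <- m + 1
  }
}

# analytic extension of a real series via the one-sided FFT spectrum;
# computed on an odd-reflection-padded 5-smooth length and truncated
analytic_series <- function(y) {
  n_orig <- length(y)
  m <- next_fast_len(n_orig)
  if (m > n_orig) {
    extra <- m - n_orig
    pad <- 2 * y[n_orig] - y[seq(n_orig - 1L, by = -1L, length.out = extra)]
    y <- c(y, pad)
  }
  z <- analytic_series_fft(y)
  z[seq_len(n_orig)]
}

analytic_series_fft <- function(y) {
  n <- length(y)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(y) * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude in a frequency band
#'
#' Band-limits the signal (see [band_limit()]) and applies the Hilbert
#' transform to obtain the analytic signal, whose argument is the
#' instantaneous phase (radians, in (-pi, pi]) and whose modulus the
#' instantaneous amplitude.
#'
#' @inheritParams band_limit
#' @return an object of class `analytic_signal` with elements `phase`,
#'   `amplitude`, `band`, `fs`, `t0`.
#' @examples
#' s <- sampled_signal(cos(2 * pi * 5 * seq(0, 4, by = 1/250)), 250)
#' a <- analytic(s, canonical_band("theta"))
#' @export
analytic <- function(x, band, fs = NULL, order = 4) {
  bl <- band_limit(x, band, fs = fs, order = order)
  z <- analytic_series(bl$x)
  structure(list(phase = Arg(z), amplitude = Mod(z), band = band,
                 fs = bl$fs, t0 = bl$t0),
            class = "analytic_signal")
}

#' @export
print.analytic_signal <- function(x, ...) {
  cat(sprintf("<analytic_signal> %d samples @ %.6g Hz, band %.6g-%.6g Hz\n",
              length(x$phase), x$fs, x$band$lo, x$band$hi))
  invisible(x)
}
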