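#' Specification of a synthetic quasi-rhythmic speech envelope
#'
#' Describes a stimulus envelope with prosodic (~1.5 Hz) and syllabic
#' (~4.5 Hz) amplitude modulation, organised into bursts of activity
#' separated by silences, so that every burst onset is a detectable temporal
#' edge. Rhythms are quasi-rhythmic, not strictly periodic: each modulation
#' cycle's duration is jittered by +/-20%.
#'
#' @param duration total duration in seconds.
#' @param fs sampling rate in Hz (default 1017, the neural recording rate).
#' @param prosody_rate prosodic modulation rate in Hz (default 1.5).
#' @param syllable_rate syllabic modulation rate in Hz (default 4.5).
#' @param n_bursts number of silence-to-burst events; default fills the
#'   duration at roughly one burst per 3.2 s.
#' @param burst_amplitudes positive per-burst amplitudes; default drawn
#'   uniformly from [0.4, 1].
#' @param silence_floor envelope value during silences (default 0.01).
#' @param seed integer RNG seed.
#' @return an object of class `envelope_spec`.
#' @export
envelope_spec <- function(duration, fs = 1017, prosody_rate = 1.5,
                          syllable_rate = 4.5, n_bursts = NULL,
                          burst_amplitudes = NULL, silence_floor = 0.01,
                          seed = 1) {
  if (duration <= 0) stop("duration must be positive")
  if (fs <= 2 * syllable_rate)
    stop("fs too low to represent the syllable rate (aliasing)")
  if (is.null(n_bursts)) n_bursts <- max(0L, floor((duration - 1) / 3.2))
  if (!is.null(burst_amplitudes)) {
    if (length(burst_amplitudes) != n_bursts)
      stop("burst_amplitudes must have length n_bursts")
    if (any(burst_amplitudes <= 0.2))
      stop("burst amplitudes must exceed 0.2 (the edge criteria need clear bursts)")
  }
  if (silence_floor < 0 || silence_floor >= 0.05)
    stop("silence_floor must be in [0, 0.05)")
  if (n_bursts > 0 && duration < 1 + 3.2 * n_bursts)
    stop("duration too short for n_bursts (need >= 1 + 3.2 * n_bursts seconds)")
  structure(list(duration = duration, fs = fs, prosody_rate = prosody_rate,
                 syllable_rate = syllable_rate, n_bursts = as.integer(n_bursts),
                 burst_amplitudes = burst_amplitudes,
                 silence_floor = silence_floor, seed = as.integer(seed)),
            class = "envelope_spec")
}

# phase track with per-cycle duration jitter (quasi-rhythmic oscillator)
jittered_phase <- function(n, rate, fs, jitter = 0.2) {
  dur <- n / fs
  n_cycles <- ceiling(dur * rate / (1 - jitter)) + 2L
  cycle_dur <- (1 / rate) * stats::runif(n_cycles, 1 - jitter, 1 + jitter)
  freq_per_cycle <- 1 / cycle_dur
  ends <- cumsum(cycle_dur)
  t <- (seq_len(n) - 1) / fs
  cyc <- findInterval(t, c(0, ends), rightmost.closed = FALSE)
  inst_freq <- freq_per_cycle[pmin(cyc, n_cycles)]
  cumsum(2 * pi * inst_freq / fs) - 2 * pi * inst_freq[1] / fs
}

#' Simulate a quasi-rhythmic speech-like envelope
#'
#' Generates the envelope described by an [envelope_spec()]: a silence floor
#' interrupted by `n_bursts` bursts. Within each burst the envelope is the
#' product of a syllabic and a prosodic raised-cosine modulator (both with
#' jittered cycle durations, both restarted at phase 0 at burst onset so the
#' onset is sharp), scaled by the burst amplitude. Spectral power is
#' concentrated below 10 Hz.
#'
#' The returned truth record stores, per burst, the gate opening time
#' (`burst_times`) and the operational edge-onset time (`edge_times`): the
#' first sample satisfying the three detection criteria of [detect_edges()]
#' on the clean normalised envelope. The windowed mean criteria begin to
#' hold a few milliseconds before the gate opens, so the two differ by up to
#' ~20 ms; downstream edge-locked analyses are defined relative to
#' `edge_times`.
#'
#' @param spec an [envelope_spec()].
#' @return list with `envelope` (a [sampled_signal()]) and `truth` (class
#'   `sim_truth`: `edge_times`, `edge_amplitudes`, `burst_times`,
#'   `burst_durations`, `envelope_seed`).
#' @export
simulate_envelope <- function(spec) {
  stopifnot(inherits(spec, "envelope_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  fs <- spec$fs
  env <- rep(spec$silence_floor, n)
  k <- spec$n_bursts
  burst_times <- burst_durs <- amps <- numeric(0)
  if (k > 0) {
    amps <- if (is.null(spec$burst_amplitudes))
      stats::runif(k, 0.4, 1) else spec$burst_amplitudes
    # layout: leading silence, then alternating burst/silence
    lead <- stats::runif(1, 0.6, 1.0)
    durs <- stats::runif(k, 1.3, 2.0)
    gaps <- stats::runif(k, 0.7, 1.2)
    starts <- lead + cumsum(c(0, durs[-k] + gaps[-k]))
    if (starts[k] + durs[k] > spec$duration - 1/fs)
      stop("internal: burst layout exceeds duration")
    for (b in seq_len(k)) {
      i0 <- round(starts[b] * fs) + 1L
      i1 <- min(n, i0 + round(durs[b] * fs) - 1L)
      m <- length(i0:i1)
      syl <- 0.5 * (1 + cos(jittered_phase(m, spec$syllable_rate, fs)))
      pros <- 0.5 * (1 + cos(jittered_phase(m, spec$prosody_rate, fs)))
      mod <- (0.35 + 0.65 * syl) * (0.6 + 0.4 * pros)
      env[i0:i1] <- spec$silence_floor + amps[b] * mod
    }
    burst_times <- (round(starts * fs)) / fs
    burst_durs <- durs
  }
  es <- sampled_signal(env, fs)
  edges <- if (k > 0) detect_edges(es) else empty_edge_list(fs)
  if (nrow(edges) != k)
    stop("internal: generator produced ", nrow(edges), " detectable edges, expected ", k)
  truth <- structure(list(edge_times = edges$onset_time,
                          edge_amplitudes = amps,
                          burst_times = burst_times,
                          burst_durations = burst_durs,
                          envelope_seed = spec$seed,
                          coupling = NULL, hemisphere = NA_character_),
                     class = "sim_truth")
  list(envelope = es, truth = truth)
}

#' Specification of the couplings injected into a synthetic neural channel
#'
#' All coupling strengths live in [0, 1]; `snr` is the linear ratio of total
#' coupled-signal power to 1/f background-noise power.
#'
#' @param phase_entrainment named numeric vector of entrainment strengths per
#'   canonical band, e.g. `c(theta = 0.8)` (names among delta/theta/gamma).
#' @param phase_lag entrainment lag in seconds (channel trails the envelope).
#' @param speechphase_to_amp strength of the modulation of channel gamma
#'   amplitude by the envelope's theta phase.
#' @param sp2a_phase_band,sp2a_amp_freq band/carrier for that modulation
#'   (defaults: theta band, 40 Hz carrier).
#' @param nested_pac list of within-channel phase-amplitude couplings, each
#'   `list(phase_band = band_spec, amp_freq = Hz, depth = [0,1])`.
#' @param edge_reset logical: reset the channel theta oscillator at each
#'   edge onset.
#' @param reset_phase0 base reset phase in radians.
#' @param reset_gain radians of reset-phase shift per unit edge amplitude.
#' @param reset_freq frequency of the resettable oscillator in Hz (default 5).
#' @param snr linear signal-to-noise power ratio (> 0; `Inf` for noiseless).
#' @param seed integer RNG seed for the channel.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(phase_entrainment = c(theta = 0),
                          phase_lag = 0,
                          speechphase_to_amp = 0,
                          sp2a_phase_band = canonical_band("theta"),
                          sp2a_amp_freq = 40,
                          nested_pac = list(),
                          edge_reset = FALSE, reset_phase0 = 0,
                          reset_gain = 0, reset_freq = 5,
                          snr = 1, seed = 1) {
  if (length(phase_entrainment) > 0) {
    if (is.null(names(phase_entrainment)) ||
        !all(names(phase_entrainment) %in% c("delta", "theta", "gamma")))
      stop("phase_entrainment must be named with canonical band names")
    if (any(phase_entrainment < 0 | phase_entrainment > 1))
      stop("entrainment strengths must be in [0, 1]")
  }
  if (speechphase_to_amp < 0 || speechphase_to_amp > 1)
    stop("speechphase_to_amp must be in [0, 1]")
  for (np in nested_pac) {
    if (is.null(np$phase_band) || is.null(np$amp_freq) || is.null(np$depth))
      stop("each nested_pac entry needs phase_band, amp_freq, depth")
    if (np$depth < 0 || np$depth > 1) stop("nested_pac depth must be in [0, 1]")
  }
  if (!(snr > 0)) stop("snr must be positive")
  structure(list(phase_entrainment = phase_entrainment, phase_lag = phase_lag,
                 speechphase_to_amp = speechphase_to_amp,
                 sp2a_phase_band = sp2a_phase_band,
                 sp2a_amp_freq = sp2a_amp_freq,
                 nested_pac = nested_pac, edge_reset = edge_reset,
                 reset_phase0 = reset_phase0, reset_gain = reset_gain,
                 reset_freq = reset_freq, snr = snr, seed = as.integer(seed)),
            class = "coupling_spec")
}

#' 1/f background noise
#'
#' Spectrally shaped white noise with power spectral density proportional to
#' 1/f^exponent, unit RMS.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param exponent spectral exponent (default 1).
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, exponent = 1) {
  m <- next_fast_len(n)   # keep the FFT length 5-smooth
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = m + 1)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]  # mirror to physical frequency
  scale <- ifelse(f < fs / m, 0, f^(-exponent / 2))
  x <- Re(stats::fft(W * scale, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

unit_rms <- function(x) {
  r <- sqrt(mean(x^2))
  if (r == 0) x else x / r
}

#' Simulate a neural-like channel coupled to a speech envelope
#'
#' Builds a channel at the envelope's sampling rate as a sum of coupled
#' components plus 1/f noise:
#' \itemize{
#'   \item phase entrainment: a band-limited, lagged copy of the envelope's
#'     band component, scaled by the strength, so the channel's band phase
#'     tracks the envelope's;
#'   \item speech-theta-phase to gamma-amplitude coupling: a gamma carrier
#'     whose amplitude is `1 + strength * cos(envelope theta phase)`;
#'   \item nested within-channel coupling: a carrier at `amp_freq` whose
#'     amplitude is `1 + depth * cos(channel low-band phase)`, where the
#'     low-band phase comes from the channel's own entrained or resettable
#'     component (an intrinsic quasi-rhythmic oscillator is added when
#'     neither exists);
#'   \item edge resets: a `reset_freq` oscillator whose phase restarts at
#'     each edge onset at `reset_phase0 + reset_gain * edge_amplitude`.
#' }
#' Component powers are fixed (entrainment components at RMS = strength,
#' reset oscillator at RMS 1, modulated carriers at RMS 0.5) and the noise
#' is scaled to yield the requested signal-to-noise power ratio.
#'
#' @param envelope a [sampled_signal()] stimulus envelope.
#' @param truth the `sim_truth` for that envelope (edge times/amplitudes).
#' @param coupling a [coupling_spec()].
#' @return a [sampled_signal()] of the same length and rate.
#' @export
simulate_channel <- function(envelope, truth, coupling) {
  stopifnot(inherits(envelope, "sampled_signal"),
            inherits(coupling, "coupling_spec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(coupling$seed)
  n <- length(envelope$x)
  fs <- envelope$fs
  t <- (seq_len(n) - 1) / fs
  sig <- numeric(n)
  low_phase <- NULL        # phase source for nested coupling
  low_band_used <- NULL

  # --- phase entrainment -------------------------------------------------
  env_c <- envelope$x - mean(envelope$x)
  pe <- coupling$phase_entrainment
  for (bn in names(pe)) {
    s <- pe[[bn]]
    if (s <= 0) next
    band <- canonical_band(bn)
    ph_env <- Arg(analytic_series(band_limit_core(env_c, band$lo, band$hi, fs)))
    lag_n <- round(coupling$phase_lag * fs)
    if (lag_n > 0) ph_env <- c(ph_env[rep(1L, lag_n)], ph_env[seq_len(n - lag_n)])
    if (lag_n < 0) ph_env <- c(ph_env[(-lag_n + 1):n], ph_env[rep(n, -lag_n)])
    # entrained intrinsic oscillation: unit amplitude, phase locked to the
    # envelope's band phase (keeps the channel phase defined in silences)
    comp <- sqrt(2) * cos(ph_env)
    sig <- sig + s * comp
    if (bn == "theta" && is.null(low_phase)) {
      low_phase <- ph_env
      low_band_used <- band
    }
  }

  # --- edge-triggered phase resets --------------------------------------
  if (isTRUE(coupling$edge_reset)) {
    f0 <- coupling$reset_freq
    phi <- 2 * pi * f0 * t + stats::runif(1, -pi, pi)
    if (length(truth$edge_times) > 0) {
      for (k in seq_along(truth$edge_times)) {
        tk <- truth$edge_times[k]
        target <- coupling$reset_phase0 +
          coupling$reset_gain * truth$edge_amplitudes[k]
        sel <- t >= tk
        phi[sel] <- target + 2 * pi * f0 * (t[sel] - tk)
      }
    }
    sig <- sig + sqrt(2) * cos(phi)   # unit RMS oscillator
    low_phase <- atan2(sin(phi), cos(phi))
    low_band_used <- band_spec(f0, 2)
  }

  # --- within-channel nested phase-amplitude coupling -------------------
  for (np in coupling$nested_pac) {
    if (np$depth <= 0) next
    pb <- np$phase_band
    ph <- low_phase
    if (is.null(ph) || is.null(low_band_used) ||
        low_band_used$center < pb$lo || low_band_used$center > pb$hi) {
      # no matching low component in the channel: add an intrinsic oscillator
      phi_i <- jittered_phase(n, pb$center, fs, jitter = 0.1) +
        stats::runif(1, -pi, pi)
      sig <- sig + sqrt(2) * cos(phi_i) * 0.7
      ph <- atan2(sin(phi_i), cos(phi_i))
      low_phase <- ph
      low_band_used <- pb
    }
    carrier <- cos(2 * pi * np$amp_freq * t + stats::runif(1, -pi, pi))
    comp <- (1 + np$depth * cos(ph)) * carrier
    sig <- sig + 0.5 * unit_rms(comp)
  }

  # --- speech theta phase -> channel gamma amplitude --------------------
  if (coupling$speechphase_to_amp > 0) {
    ph_env <- Arg(analytic_series(
      band_limit_core(env_c, coupling$sp2a_phase_band$lo,
                      coupling$sp2a_phase_band$hi, fs)))
    carrier <- cos(2 * pi * coupling$sp2a_amp_freq * t + stats::runif(1, -pi, pi))
    comp <- (1 + coupling$speechphase_to_amp * cos(ph_env)) * carrier
    sig <- sig + 0.5 * unit_rms(comp)
  }

  # --- 1/f background ----------------------------------------------------
  p_sig <- mean(sig^2)
  if (is.infinite(coupling$snr)) {
    out <- if (p_sig > 0) sig else stop("snr = Inf with no coupled components")
  } else {
    noise <- pink_noise(n, fs)
    noise_rms <- if (p_sig > 0) sqrt(p_sig / coupling$snr) else 1
    out <- sig + noise_rms * noise
  }
  sampled_signal(out, fs, envelope$t0)
}

#' Simulate a cohort of participants with left and right channels
#'
#' Every participant hears the same stimulus (one shared envelope, as in a
#' single-story listening study); the neural channels differ by
#' participant-specific seeds derived deterministically from the master
#' seed. When `out_dir` is given, one directory per participant is written
#' containing `envelope.csv`, `left.csv`, `right.csv` (single column with a
#' `# fs=` header) plus a top-level `truth.json` manifest; the manifest
#' labels all generator choices as synthetic stand-ins.
#'
#' @param n_participants number of participants (>= 2).
#' @param left_spec,right_spec [coupling_spec()]s for the two hemispheres
#'   (their `seed` fields are overridden per participant).
#' @param spec an [envelope_spec()] for the shared stimulus.
#' @param master_seed integer master seed.
#' @param out_dir optional output directory; `NULL` keeps everything in
#'   memory.
#' @return (invisibly when writing) a list with `envelope`, `truth`,
#'   `participants` (each: `id`, `left`, `right` sampled signals, seeds),
#'   and `manifest`.
#' @export
simulate_cohort <- function(n_participants, left_spec, right_spec, spec,
                            master_seed = 1, out_dir = NULL) {
  if (n_participants < 2L) stop("need at least 2 participants")
  sim <- simulate_envelope(spec)
  participants <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    ls <- left_spec; ls$seed <- as.integer(master_seed * 131L + i * 2L) %% 2147483647L
    rs <- right_spec; rs$seed <- as.integer(master_seed * 131L + i * 2L + 1L) %% 2147483647L
    participants[[i]] <- list(
      id = sprintf("P%02d", i),
      left = simulate_channel(sim$envelope, sim$truth, ls),
      right = simulate_channel(sim$envelope, sim$truth, rs),
      left_seed = ls$seed, right_seed = rs$seed)
  }
  manifest <- list(
    generator = "synthetic stand-in (no generative model is claimed for real recordings)",
    n_participants = n_participants,
    fs = spec$fs,
    master_seed = master_seed,
    envelope = list(seed = spec$seed,
                    edge_times = sim$truth$edge_times,
                    edge_amplitudes = sim$truth$edge_amplitudes,
                    burst_times = sim$truth$burst_times),
    left_spec = strip_spec(left_spec), right_spec = strip_spec(right_spec),
    participant_seeds = lapply(participants, function(p)
      list(id = p$id, left = p$left_seed, right = p$right_seed)))
  out <- list(envelope = sim$envelope, truth = sim$truth,
              participants = participants, manifest = manifest)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory ", out_dir)
    for (p in participants) {
      d <- file.path(out_dir, p$id)
      dir.create(d, showWarnings = FALSE)
      write_signal_csv(sim$envelope, file.path(d, "envelope.csv"))
      write_signal_csv(p$left, file.path(d, "left.csv"))
      write_signal_csv(p$right, file.path(d, "right.csv"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(out))
  }
  out
}

strip_spec <- function(cs) {
  list(phase_entrainment = as.list(cs$phase_entrainment),
       phase_lag = cs$phase_lag,
       speechphase_to_amp = cs$speechphase_to_amp,
       nested_pac = lapply(cs$nested_pac, function(np)
         list(phase_band = c(np$phase_band$lo, np$phase_band$hi),
              amp_freq = np$amp_freq, depth = np$depth)),
       edge_reset = cs$edge_reset, reset_phase0 = cs$reset_phase0,
       reset_gain = cs$reset_gain, snr = cs$snr)
}
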