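#' Mutual information between speech and brain signals
#'
#' Selects the phase or amplitude component of each analytic signal per the
#' requested mode, quantises each into equipopulated bins, and returns the
#' bias-corrected (quadratic extrapolation) MI in bits.
#'
#' @param speech,brain [analytic()] signals of equal length and sampling
#'   rate. For the within-frequency modes (`phase-phase`, `amp-amp`) the two
#'   bands must match.
#' @param mode one of `"phase-phase"`, `"phase-amp"`, `"amp-phase"`,
#'   `"amp-amp"` (speech component named first).
#' @param n_bins equipopulated bins per variable (default 10).
#' @param bias_correct use quadratic extrapolation (default TRUE).
#' @param discard margin in seconds removed at each end before binning, to
#'   drop filter transients (default 1; set 0 to keep everything).
#' @return an `mi_estimate`.
#' @export
speech_brain_mi <- function(speech, brain,
                            mode = c("phase-phase", "phase-amp",
                                     "amp-phase", "amp-amp"),
                            n_bins = 10, bias_correct = TRUE, discard = 1) {
  mode <- match.arg(mode)
  if (!inherits(speech, "analytic_signal") || !inherits(brain, "analytic_signal"))
    stop("speech and brain must be analytic_signal objects")
  if (speech$fs != brain$fs) stop("sampling rates differ")
  if (length(speech$phase) != length(brain$phase)) stop("length mismatch")
  parts <- strsplit(mode, "-")[[1]]
  if (parts[1] == parts[2] &&
      (abs(speech$band$lo - brain$band$lo) > 1e-9 ||
       abs(speech$band$hi - brain$band$hi) > 1e-9))
    stop("within-frequency mode requires matching bands")
  pick <- function(sig, what) if (what == "phase") sig$phase else sig$amplitude
  sv <- pick(speech, parts[1])
  bv <- pick(brain, if (parts[2] == "amp") "amplitude" else "phase")
  keep <- trim_margin(length(sv), speech$fs, discard)
  bs <- equipopulated_bin(sv[keep], n_bins)
  bb <- equipopulated_bin(bv[keep], n_bins)
  if (bias_correct) mi_qe(bs, bb) else mi_plugin(bs, bb)
}

trim_margin <- function(n, fs, discard) {
  m <- round(discard * fs)
  if (2 * m + 16 >= n) seq_len(n) else (m + 1L):(n - m)
}

#' Speech-brain coupling spectrum over a frequency scan
#'
#' Band-limits both signals at each centre frequency with [default_band()]
#' (+/-1 Hz up to 40 Hz, +/-5 Hz above), extracts phase or amplitude, and
#' computes the bias-corrected MI per frequency. Optional surrogates use the
#' time-reversed envelope ([surrogate_reversed()]), each giving a chance-level
#' MI per frequency.
#'
#' @param env speech envelope as a [sampled_signal()].
#' @param brain neural channel as a [sampled_signal()] (same fs and length).
#' @param freqs centre frequencies in Hz (default 1:60).
#' @param mode as in [speech_brain_mi()].
#' @param n_bins bins per variable.
#' @param n_surrogates reversed-envelope surrogates per frequency (default 0;
#'   the single reversed envelope is deterministic, so values > 1 add
#'   random circular shifts of the reversed envelope).
#' @param seed RNG seed for surrogate shifts.
#' @return a `coupling_result`: data frame `spectrum` (freq, mi, mi_plugin),
#'   matrix `surrogate_mi` (freq x surrogate) or NULL, and settings.
#' @export
coupling_spectrum <- function(env, brain, freqs = 1:60,
                              mode = "phase-phase", n_bins = 10,
                              n_surrogates = 0, seed = 1) {
  if (env$fs != brain$fs) stop("sampling rates differ")
  n <- length(env$x)
  if (n != length(brain$x)) stop("length mismatch")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  shifts <- if (n_surrogates > 0)
    c(0, sample.int(n - 2L, max(0, n_surrogates - 1L))) else integer(0)
  rev_env <- surrogate_reversed(env)
  mi <- mi_pl <- numeric(length(freqs))
  surr <- if (n_surrogates > 0)
    matrix(NA_real_, length(freqs), n_surrogates) else NULL
  for (k in seq_along(freqs)) {
    band <- default_band(freqs[k])
    a_env <- analytic(env, band)
    a_brain <- analytic(brain, band)
    est <- speech_brain_mi(a_env, a_brain, mode, n_bins = n_bins)
    mi[k] <- est$mi; mi_pl[k] <- est$mi_plugin
    if (n_surrogates > 0) {
      a_rev <- analytic(rev_env, band)
      for (s in seq_len(n_surrogates)) {
        shifted <- shift_analytic(a_rev, shifts[s])
        surr[k, s] <- speech_brain_mi(shifted, a_brain, mode,
                                      n_bins = n_bins)$mi
      }
    }
  }
  structure(list(mode = mode,
                 spectrum = data.frame(freq = freqs, mi = mi, mi_plugin = mi_pl),
                 surrogate_mi = surr, n_bins = n_bins,
                 n_surrogates = n_surrogates),
            class = "coupling_result")
}

shift_analytic <- function(a, k) {
  if (k == 0) return(a)
  n <- length(a$phase)
  idx <- c((k + 1L):n, 1:k)
  a$phase <- a$phase[idx]; a$amplitude <- a$amplitude[idx]
  a
}

#' @export
print.coupling_result <- function(x, ...) {
  if (!is.null(x$spectrum)) {
    pk <- x$spectrum[which.max(x$spectrum$mi), ]
    cat(sprintf("<coupling_result> mode %s, %d frequencies, peak %.4f bits @ %g Hz\n",
                x$mode, nrow(x$spectrum), pk$mi, pk$freq))
  } else {
    cat(sprintf("<coupling_result> comodulogram %d phase x %d amplitude frequencies\n",
                length(x$phase_freqs), length(x$amp_freqs)))
  }
  invisible(x)
}

#' Within-signal cross-frequency (phase-amplitude) coupling
#'
#' MI between the low-band instantaneous phase and the high-band
#' instantaneous amplitude of the same signal, both quantised into
#' equipopulated bins.
#'
#' @param x a [sampled_signal()].
#' @param phase_band,amp_band [band_spec()]s; `amp_band` must be centred
#'   above `phase_band`.
#' @param n_bins bins per variable (default 10).
#' @param bias_correct use quadratic extrapolation (default TRUE).
#' @param discard edge margin in seconds (default 1).
#' @return an `mi_estimate`.
#' @export
cross_frequency_mi <- function(x, phase_band, amp_band, n_bins = 10,
                               bias_correct = TRUE, discard = 1) {
  if (amp_band$center <= phase_band$center)
    stop("amp_band must be centred above phase_band")
  ap <- analytic(x, phase_band)
  aa <- analytic(x, amp_band)
  keep <- trim_margin(length(ap$phase), x$fs, discard)
  amp <- aa$amplitude[keep]
  if (mean(amp) <= 0 || stats::sd(amp) / mean(amp) < 0.05) {
    warning("degenerate (near-constant) amplitude; phase-amplitude MI is not meaningful")
  }
  bp <- equipopulated_bin(ap$phase[keep], n_bins)
  ba <- suppressWarnings(equipopulated_bin(amp, n_bins))
  if (bias_correct) mi_qe(bp, ba) else mi_plugin(bp, ba)
}

#' Cross-frequency comodulogram
#'
#' MI between low-band phase and high-band amplitude over a grid of phase
#' frequencies (default 1-10 Hz) and amplitude frequencies (default 4-80 Hz),
#' with a per-cell surrogate significance mask. Surrogates circularly shift
#' the amplitude bin labels by random offsets of at least `min_shift`
#' seconds, which preserves both marginals while destroying the phase-
#' amplitude alignment.
#'
#' @param x a [sampled_signal()] (fs > 160 Hz for the default grid).
#' @param phase_freqs,amp_freqs centre frequencies in Hz.
#' @param n_bins bins per variable.
#' @param n_surrogates surrogates per cell (default 100).
#' @param min_shift minimum circular shift in seconds (default 1).
#' @param seed RNG seed for the surrogate shifts.
#' @param discard edge margin in seconds (default 1).
#' @return a `coupling_result` with `mi` (phase x amp matrix, bias-corrected),
#'   `surrogate_q95` (per-cell surrogate 95th percentile), `mask`
#'   (`mi > surrogate_q95`), and the axes.
#' @export
comodulogram <- function(x, phase_freqs = 1:10, amp_freqs = seq(4, 80, by = 4),
                         n_bins = 10, n_surrogates = 100, min_shift = 1,
                         seed = 1, discard = 1) {
  if (x$fs <= 2 * (max(amp_freqs) + 5))
    stop("sampling rate too low for the amplitude frequency grid")
  keep <- trim_margin(length(x$x), x$fs, discard)
  phase_labels <- lapply(phase_freqs, function(f)
    equipopulated_bin(analytic(x, default_band(f))$phase[keep], n_bins))
  amp_labels <- lapply(amp_freqs, function(f)
    equipopulated_bin(analytic(x, default_band(f))$amplitude[keep], n_bins))
  n <- length(keep)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  m_shift <- round(min_shift * x$fs)
  if (n_surrogates > 0 && n <= 2 * m_shift)
    stop("signal too short for the surrogate shift range")
  shifts <- if (n_surrogates > 0)
    sample(seq.int(m_shift, n - m_shift), n_surrogates, replace = TRUE)
  else integer(0)
  np <- length(phase_freqs); na <- length(amp_freqs)
  mi <- mi_pl <- q95 <- matrix(NA_real_, np, na,
                               dimnames = list(phase_freqs, amp_freqs))
  for (i in seq_len(np)) {
    bp <- phase_labels[[i]]
    for (j in seq_len(na)) {
      ba <- amp_labels[[j]]
      est <- mi_qe(bp, ba)
      mi[i, j] <- est$mi
      mi_pl[i, j] <- est$mi_plugin
      if (n_surrogates > 0) {
        surr <- vapply(shifts, function(s) {
          lab <- ba$labels[c((s + 1L):n, 1:s)]
          mi_from_labels(bp$labels, lab, n_bins, n_bins)
        }, numeric(1))
        q95[i, j] <- stats::quantile(surr, 0.95, names = FALSE)
      }
    }
  }
  # the mask compares plug-in against plug-in surrogates: same estimator on
  # both sides keeps the nominal false-positive rate
  structure(list(mode = "phase-amp", phase_freqs = phase_freqs,
                 amp_freqs = amp_freqs, mi = mi, mi_plugin = mi_pl,
                 surrogate_q95 = q95,
                 mask = if (n_surrogates > 0) mi_pl > q95 else NULL,
                 n_bins = n_bins, n_surrogates = n_surrogates),
            class = "coupling_result")
}

#' Time-reversed envelope surrogate
#'
#' Reversing the speech envelope in time preserves its spectrum and
#' amplitude distribution but destroys the temporal correspondence with the
#' brain signal; MI against the reversed envelope estimates chance level.
#'
#' @param env a [sampled_signal()].
#' @return a [sampled_signal()] with the samples reversed.
#' @export
surrogate_reversed <- function(env) {
  sampled_signal(rev(env$x), env$fs, env$t0)
}

#' Random trial-mismatch pairing for epoched surrogates
#'
#' Returns a derangement of trial indices (no trial maps to itself), used to
#' pair each amplitude trial with the phase signal of a different, random
#' trial when building comodulogram nulls from epoched data.
#'
#' @param n_trials number of trials (>= 2).
#' @param seed RNG seed.
#' @return integer permutation of `1:n_trials` with no fixed points.
#' @export
surrogate_trial_mismatch <- function(n_trials, seed = 1) {
  if (n_trials < 2L) stop("need at least 2 trials")
  if (n_trials == 2L) return(c(2L, 1L))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  repeat {
    perm <- sample(n_trials)
    if (all(perm != seq_len(n_trials))) return(perm)
  }
}
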