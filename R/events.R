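#' Detect temporal edges (onsets) in a speech envelope
#'
#' The envelope is first normalised to a maximum of 1. A sample at time t is
#' an edge onset when all three criteria hold:
#' \enumerate{
#'   \item mean amplitude in the 400 ms before t is below `amp_threshold`;
#'   \item mean amplitude in the 1 s after t is above `amp_threshold`;
#'   \item the mean amplitude in the 20 ms after t exceeds the mean in the
#'     20 ms before t by more than `amp_threshold`.
#' }
#' The onset is the first sample at which all criteria hold; subsequent
#' candidates within `refractory` seconds of an accepted onset are
#' suppressed. Per edge, the maximum normalised amplitude within 200 ms
#' after onset and the mean and maximum slope within 100 ms after onset are
#' recorded.
#'
#' @param env a [sampled_signal()], non-negative.
#' @param amp_threshold criterion threshold on the normalised envelope
#'   (default 0.05).
#' @param pre_silence,post_active,step_halfwin criterion window lengths in
#'   seconds (defaults 0.4, 1, 0.02).
#' @param refractory suppression gap after an accepted onset in seconds
#'   (default 0.4).
#' @return an object of class `edge_list`: a data frame with columns
#'   `onset_time`, `onset_index`, `max_amp_200ms`, `mean_slope_100ms`,
#'   `max_slope_100ms`; zero rows when no edge qualifies.
#' @export
detect_edges <- function(env, amp_threshold = 0.05, pre_silence = 0.4,
                         post_active = 1, step_halfwin = 0.02,
                         refractory = 0.4) {
  if (!inherits(env, "sampled_signal")) stop("env must be a sampled_signal")
  x <- env$x
  if (any(x < 0)) stop("envelope must be non-negative")
  if (signal_duration(env) <= pre_silence + post_active)
    stop("envelope shorter than the criterion windows")
  fs <- env$fs
  if (max(x) == 0) {
    warning("all-zero envelope: no edges")
    return(empty_edge_list(fs))
  }
  x <- x / max(x)
  n <- length(x)
  n_pre <- round(pre_silence * fs)
  n_post <- round(post_active * fs)
  n_step <- round(step_halfwin * fs)

  cs <- c(0, cumsum(x))
  win_mean <- function(from, len) (cs[from + len] - cs[from]) / len
  # valid onset candidates: full windows on both sides
  i <- seq.int(n_pre + 1L, n - n_post + 1L)
  ok <- win_mean(i - n_pre, n_pre) < amp_threshold &
        win_mean(i, n_post) > amp_threshold &
        (win_mean(i, n_step) - win_mean(i - n_step, n_step)) > amp_threshold
  cand <- i[ok]
  onsets <- integer(0)
  last <- -Inf
  for (ci in cand) {
    if (ci - last > refractory * fs) {
      onsets <- c(onsets, ci)
      last <- ci
    }
  }
  if (length(onsets) == 0L) return(empty_edge_list(fs))
  n200 <- round(0.2 * fs)
  n100 <- round(0.1 * fs)
  slope <- diff(x) * fs
  feat <- t(vapply(onsets, function(o) {
    a200 <- x[o:min(n, o + n200 - 1L)]
    sl <- slope[o:min(length(slope), o + n100 - 1L)]
    c(max(a200), mean(sl), max(sl))
  }, numeric(3)))
  structure(data.frame(onset_time = (onsets - 1) / fs + env$t0,
                       onset_index = onsets,
                       max_amp_200ms = feat[, 1],
                       mean_slope_100ms = feat[, 2],
                       max_slope_100ms = feat[, 3]),
            class = c("edge_list", "data.frame"), fs = fs)
}

empty_edge_list <- function(fs) {
  structure(data.frame(onset_time = numeric(0), onset_index = integer(0),
                       max_amp_200ms = numeric(0), mean_slope_100ms = numeric(0),
                       max_slope_100ms = numeric(0)),
            class = c("edge_list", "data.frame"), fs = fs)
}

#' Cut a signal into trials around event onsets
#'
#' Extracts one row per onset over a common window relative to the onset
#' (default -500 ms to 1000 ms). Onsets whose window would run outside the
#' signal are dropped with a message.
#'
#' @param x a [sampled_signal()], an `analytic_signal` component (pass
#'   `component = "phase"` or `"amplitude"`), or a numeric vector with `fs`.
#' @param onsets an `edge_list` from [detect_edges()], or a numeric vector of
#'   onset times in seconds.
#' @param window two-element numeric, window in seconds relative to onset
#'   (`window[1] < 0 < window[2]`).
#' @param component which component to epoch when `x` is an
#'   `analytic_signal`.
#' @param fs sampling rate when `x` is a bare numeric vector.
#' @return an object of class `epoch_set`: `data` (trials x samples matrix),
#'   `times` (seconds relative to onset), `fs`, `window`, `onset_times`
#'   (the onsets kept), `n_dropped`.
#' @export
epoch <- function(x, onsets, window = c(-0.5, 1), component = c("phase", "amplitude"),
                  fs = NULL) {
  if (inherits(x, "analytic_signal")) {
    component <- match.arg(component)
    v <- x[[component]]; fs <- x$fs; t0 <- x$t0
  } else if (inherits(x, "sampled_signal")) {
    v <- x$x; fs <- x$fs; t0 <- x$t0
  } else {
    if (is.null(fs)) stop("fs required for a bare numeric vector")
    v <- x; t0 <- 0
  }
  if (window[1] >= 0 || window[2] <= 0) stop("window must straddle 0")
  times <- if (inherits(onsets, "edge_list")) onsets$onset_time else as.numeric(onsets)
  i_on <- round((times - t0) * fs) + 1L
  rel <- seq.int(round(window[1] * fs), round(window[2] * fs))
  keep <- i_on + rel[1] >= 1L & i_on + rel[length(rel)] <= length(v)
  if (!all(keep))
    message(sum(!keep), " onset(s) too close to the signal boundary dropped")
  if (!any(keep)) stop("no usable onsets within the signal")
  i_on <- i_on[keep]
  data <- t(vapply(i_on, function(o) v[o + rel], numeric(length(rel))))
  structure(list(data = data, times = rel / fs, fs = fs, window = window,
                 onset_times = times[keep], n_dropped = sum(!keep)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d samples, window [%g, %g] s @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$window[1], x$window[2], x$fs))
  invisible(x)
}

plv_series <- function(values, times, variant, n_trials) {
  structure(list(values = values, times = times, variant = variant,
                 n_trials = n_trials),
            class = "plv_series")
}

#' @export
print.plv_series <- function(x, ...) {
  cat(sprintf("<plv_series> variant '%s', %d trials, mean PLV %.3f\n",
              x$variant, x$n_trials, mean(x$values)))
  invisible(x)
}

check_phase_epochs <- function(e) {
  if (!inherits(e, "epoch_set")) stop("expected an epoch_set")
  if (any(!is.finite(e$data))) stop("non-finite phase values")
  e
}

#' Phase-locking value across trials
#'
#' PLV(t) = |mean over trials of exp(i ph(t))|: the modulus of the mean unit
#' phasor at each time point. 1 means identical phase in every trial;
#' chance level for n uniform trials is about sqrt(pi) / (2 sqrt(n)).
#'
#' @param phase_epochs an [epoch()] set of phase values (radians).
#' @return a `plv_series` (values in [0, 1] per time point).
#' @export
plv_across_trials <- function(phase_epochs) {
  e <- check_phase_epochs(phase_epochs)
  if (nrow(e$data) < 2L) stop("need at least 2 trials")
  v <- Mod(colMeans(exp(1i * e$data)))
  plv_series(v, e$times, "across_trials", nrow(e$data))
}

#' Phase-locking between brain and speech phase
#'
#' PLV of the per-trial phase difference, |mean exp(i (ph - phs))|, which is
#' high when the brain phase tracks the speech phase with a consistent lag.
#'
#' @param brain_phase,speech_phase [epoch()] sets of phase values with
#'   matching trial counts and windows.
#' @return a `plv_series`.
#' @export
plv_speech_brain <- function(brain_phase, speech_phase) {
  b <- check_phase_epochs(brain_phase); s <- check_phase_epochs(speech_phase)
  if (!identical(dim(b$data), dim(s$data))) stop("trial/window mismatch")
  v <- Mod(colMeans(exp(1i * (b$data - s$data))))
  plv_series(v, b$times, "speech_brain", nrow(b$data))
}

#' Phase-locking between homologous left and right channels
#'
#' PLV of the per-trial left-minus-right phase difference.
#'
#' @param left_phase,right_phase [epoch()] sets of phase values with matching
#'   trial counts and windows.
#' @return a `plv_series`.
#' @export
plv_between_channels <- function(left_phase, right_phase) {
  l <- check_phase_epochs(left_phase); r <- check_phase_epochs(right_phase)
  if (!identical(dim(l$data), dim(r$data))) stop("trial/window mismatch")
  v <- Mod(colMeans(exp(1i * (l$data - r$data))))
  plv_series(v, l$times, "between_channels", nrow(l$data))
}

#' Mean PLV in named time windows
#'
#' Averages a time-resolved PLV series in a set of windows relative to onset;
#' defaults are a pre-onset baseline (-200 to 0 ms), an early (100-300 ms)
#' and a late (400-600 ms) window.
#'
#' @param plv a `plv_series`.
#' @param windows named list of two-element windows in seconds.
#' @return named numeric vector of per-window mean PLV.
#' @export
window_stats <- function(plv, windows = list(baseline = c(-0.2, 0),
                                             early = c(0.1, 0.3),
                                             late = c(0.4, 0.6))) {
  vapply(windows, function(w) {
    sel <- plv$times >= w[1] & plv$times <= w[2]
    if (!any(sel)) stop("window [", w[1], ", ", w[2], "] outside the epoch")
    mean(plv$values[sel])
  }, numeric(1))
}

#' Oscillatory sampling: trial-wise cross-correlation with the envelope
#'
#' For each trial, correlates cos(phase) (or amplitude) of a cortical band
#' with the speech envelope over 0-500 ms after onset, at lags up to
#' +/-150 ms, takes the maximum absolute correlation across lags, and
#' averages over trials. With `shuffle = TRUE` the envelope trial order is
#' randomly permuted first (never the identity), destroying the per-trial
#' correspondence and giving the chance level.
#'
#' @param brain_epochs [epoch()] set of the brain phase (radians) or
#'   amplitude, as selected by `mode`.
#' @param env_epochs [epoch()] set of the speech envelope with the same
#'   trials and window.
#' @param mode `"phase"` (correlate cos of `brain_epochs` values) or
#'   `"amplitude"` (correlate them as-is).
#' @param shuffle permute the envelope trial order first.
#' @param seed RNG seed used when `shuffle = TRUE`.
#' @param range correlation window in seconds relative to onset (default
#'   `c(0, 0.5)`).
#' @param max_lag maximum lag in seconds (default 0.15).
#' @return list with `mean_max_r` (mean over trials of max |r|), `per_trial`
#'   (max |r| per trial), `n_excluded` (degenerate trials dropped).
#' @export
sampling_correlation <- function(brain_epochs, env_epochs,
                                 mode = c("phase", "amplitude"),
                                 shuffle = FALSE, seed = 1,
                                 range = c(0, 0.5), max_lag = 0.15) {
  mode <- match.arg(mode)
  b <- brain_epochs; e <- env_epochs
  if (!identical(dim(b$data), dim(e$data))) stop("trial/window mismatch")
  if (nrow(b$data) < 10L) stop("need at least 10 trials")
  fs <- b$fs
  sel <- which(b$times >= range[1] & b$times <= range[2])
  lag_n <- round(max_lag * fs)
  bm <- if (mode == "phase") cos(b$data) else b$data
  em <- e$data
  order_env <- seq_len(nrow(em))
  if (shuffle) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    repeat {
      order_env <- sample(nrow(em))
      if (any(order_env != seq_len(nrow(em)))) break
    }
  }
  lags <- seq.int(-lag_n, lag_n)
  n_excluded <- 0L
  per_trial <- rep(NA_real_, nrow(bm))
  for (tr in seq_len(nrow(bm))) {
    bv <- bm[tr, sel]
    ev_full <- em[order_env[tr], ]
    if (stats::sd(bv) == 0) { n_excluded <- n_excluded + 1L; next }
    rmax <- 0
    for (lg in lags) {
      idx <- sel + lg
      valid <- idx >= 1L & idx <= ncol(em)
      ev <- ev_full[idx[valid]]
      if (stats::sd(ev) == 0) next
      r <- abs(stats::cor(bv[valid], ev))
      if (is.finite(r) && r > rmax) rmax <- r
    }
    per_trial[tr] <- rmax
  }
  if (n_excluded > 0) message(n_excluded, " degenerate trial(s) excluded")
  kept <- !is.na(per_trial)
  list(mean_max_r = mean(per_trial[kept]), per_trial = per_trial,
       n_excluded = n_excluded)
}

#' Circular-linear correlation
#'
#' Correlation between a circular variable (radians) and a linear variable,
#' via the embedding formula
#' r^2 = (r_cx^2 + r_sx^2 - 2 r_cx r_sx r_cs) / (1 - r_cs^2)
#' with r_cx = cor(cos theta, x), r_sx = cor(sin theta, x),
#' r_cs = cor(cos theta, sin theta).
#'
#' @param theta circular variable in radians.
#' @param x linear variable, same length.
#' @return r in [0, 1].
#' @export
circ_lin_corr <- function(theta, x) {
  rcx <- stats::cor(cos(theta), x)
  rsx <- stats::cor(sin(theta), x)
  rcs <- stats::cor(cos(theta), sin(theta))
  r2 <- (rcx^2 + rsx^2 - 2 * rcx * rsx * rcs) / (1 - rcs^2)
  sqrt(max(0, min(1, r2)))
}

#' Phase coding of edge amplitude
#'
#' Tests whether the oscillatory phase at a fixed latency after edge onset
#' (default 100 ms) codes the edge amplitude (maximum normalised envelope in
#' the 200 ms after onset), using circular-linear correlation with a
#' permutation p-value.
#'
#' @param theta_phase_epochs [epoch()] set of phase values whose trials
#'   correspond row-for-row to `edges`.
#' @param edges an `edge_list` from [detect_edges()] (its `max_amp_200ms`
#'   column is the linear variable). A bare numeric vector of amplitudes is
#'   also accepted.
#' @param at latency after onset at which the phase is read out, in seconds.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list with `r`, `p_value`, `phase_at` (per-trial phases),
#'   `amplitudes`.
#' @export
phase_amplitude_coding <- function(theta_phase_epochs, edges, at = 0.1,
                                   n_perm = 1000, seed = 1) {
  e <- check_phase_epochs(theta_phase_epochs)
  amp <- if (inherits(edges, "edge_list") || is.data.frame(edges))
    edges$max_amp_200ms else as.numeric(edges)
  if (nrow(e$data) != length(amp)) stop("trial count mismatch with edges")
  if (nrow(e$data) < 10L) stop("need at least 10 trials")
  j <- which.min(abs(e$times - at))
  ph <- e$data[, j]
  r_obs <- circ_lin_corr(ph, amp)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  r_null <- vapply(seq_len(n_perm),
                   function(k) circ_lin_corr(ph, sample(amp)), numeric(1))
  p <- (1 + sum(r_null >= r_obs)) / (n_perm + 1)
  list(r = r_obs, p_value = p, phase_at = ph, amplitudes = amp)
}

#' Edge-locked change in cross-frequency coupling
#'
#' For each trial, computes the plug-in MI between low-band phase and
#' high-band amplitude separately in a pre-onset and a post-onset window
#' (default -500-0 ms and 0-500 ms), then a paired t-statistic of the
#' post-versus-pre contrast across trials. Within a 500 ms window only a few
#' hundred samples are available, so 4 equipopulated bins per variable are
#' used by default rather than the 10 used for continuous data; when even
#' that is unsupported the bin count is reduced further with a message.
#'
#' @param phase_epochs,amp_epochs [epoch()] sets of the phase and amplitude
#'   series (matching trials and windows).
#' @param pre_window,post_window two-element windows in seconds (equal
#'   lengths).
#' @param n_bins equipopulated bins per variable (default 4).
#' @return list with `t`, `p_value`, `df`, `mi_pre`, `mi_post` (per-trial
#'   plug-in MI), `n_bins`.
#' @export
edge_locked_pac <- function(phase_epochs, amp_epochs,
                            pre_window = c(-0.5, 0), post_window = c(0, 0.5),
                            n_bins = 4) {
  p <- check_phase_epochs(phase_epochs); a <- amp_epochs
  if (!identical(dim(p$data), dim(a$data))) stop("trial/window mismatch")
  if (abs(diff(pre_window) - diff(post_window)) > 1e-9)
    stop("pre and post windows must have equal length")
  sel_pre <- p$times >= pre_window[1] & p$times < pre_window[2]
  sel_post <- p$times >= post_window[1] & p$times < post_window[2]
  n_win <- sum(sel_pre)
  while (n_bins > 2L && n_win < 10L * n_bins * n_bins) {
    n_bins <- n_bins - 1L
    message("window too short; reducing bins to ", n_bins)
  }
  trial_mi <- function(sel) {
    vapply(seq_len(nrow(p$data)), function(tr) {
      bp <- equipopulated_bin(p$data[tr, sel], n_bins)
      ba <- equipopulated_bin(a$data[tr, sel], n_bins)
      mi_plugin(bp, ba)$mi
    }, numeric(1))
  }
  mi_pre <- trial_mi(sel_pre)
  mi_post <- trial_mi(sel_post)
  tt <- stats::t.test(mi_post, mi_pre, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mi_pre = mi_pre, mi_post = mi_post,
       n_bins = n_bins)
}
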