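#' Default run configuration
#'
#' Collects every numeric analysis setting into one declarative record, with
#' the canonical defaults: 10 equipopulated bins, quadratic-extrapolation
#' bias correction, edge criteria thresholds 0.05 / 400 ms / 1 s / 20 ms,
#' epoch window -500 to 1000 ms, PLV windows baseline/early/late, 500
#' randomisations, 500 bootstrap iterations, FDR level 0.05. A bare
#' `default_config()` therefore reproduces the canonical analysis settings
#' on a simulated cohort.
#'
#' @param master_seed integer master seed for the whole run.
#' @param out_dir optional output directory for the report tables.
#' @param ... named overrides of any top-level config entry.
#' @return a list of class `run_config`.
#' @export
default_config <- function(master_seed = 1, out_dir = NULL, ...) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    out_dir = out_dir,
    input_dir = NULL,                 # read a cohort from disk instead
    simulation = list(
      n_participants = 22,
      duration = 40,
      fs = 1017,
      n_bursts = 11,
      left = list(theta_entrainment = 0.4, nested_pac_depth = 0.6,
                  edge_reset = TRUE, reset_gain = pi / 2, snr = 1),
      right = list(theta_entrainment = 0.8, nested_pac_depth = 0.3,
                   edge_reset = TRUE, reset_gain = pi / 2, snr = 1)),
    mi = list(n_bins = 10, bias_correct = TRUE, discard = 1),
    edges = list(amp_threshold = 0.05, pre_silence = 0.4, post_active = 1,
                 step_halfwin = 0.02),
    epoch_window = c(-0.5, 1),
    plv_windows = list(baseline = c(-0.2, 0), early = c(0.1, 0.3),
                       late = c(0.4, 0.6)),
    stats = list(n_rand = 500, q = 0.05, n_boot = 500),
    complementarity = list(enable = TRUE, n_shuffles = 200),
    sampling = list(enable = TRUE, max_lag = 0.15, range = c(0, 0.5)),
    comodulogram = list(enable = FALSE, phase_freqs = 1:10,
                        amp_freqs = seq(4, 80, by = 4), n_surrogates = 100)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with any subset of the [default_config()] entries;
#'   missing entries take their defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_in(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  structure(merge_in(unclass(cfg), user), class = "run_config")
}

# small rolling hash of the serialised config, for table provenance
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(unclass(cfg), NULL))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

pkg_version <- function() as.character(utils::packageVersion("oscitrack"))

cohort_from_config <- function(cfg) {
  sim <- cfg$simulation
  spec <- envelope_spec(duration = sim$duration, fs = sim$fs,
                        n_bursts = sim$n_bursts,
                        seed = cfg$master_seed)
  build_spec <- function(side, seed_off) {
    coupling_spec(
      phase_entrainment = c(theta = side$theta_entrainment),
      speechphase_to_amp = if (!is.null(side$speechphase_to_amp))
        side$speechphase_to_amp else 0,
      nested_pac = if (side$nested_pac_depth > 0)
        list(list(phase_band = canonical_band("theta"), amp_freq = 40,
                  depth = side$nested_pac_depth)) else list(),
      edge_reset = isTRUE(side$edge_reset),
      reset_gain = if (!is.null(side$reset_gain)) side$reset_gain else 0,
      snr = side$snr, seed = cfg$master_seed + seed_off)
  }
  simulate_cohort(sim$n_participants,
                  build_spec(sim$left, 7L), build_spec(sim$right, 11L),
                  spec, master_seed = cfg$master_seed,
                  out_dir = NULL)
}

load_cohort <- function(input_dir) {
  dirs <- sort(list.dirs(input_dir, recursive = FALSE))
  if (length(dirs) == 0) stop("no participant directories in ", input_dir)
  participants <- lapply(seq_along(dirs), function(i) {
    list(id = basename(dirs[i]),
         left = read_signal_csv(file.path(dirs[i], "left.csv")),
         right = read_signal_csv(file.path(dirs[i], "right.csv")))
  })
  env <- read_signal_csv(file.path(dirs[1], "envelope.csv"))
  list(envelope = env, truth = NULL, participants = participants,
       manifest = NULL)
}

#' Run the full analysis pipeline on a cohort
#'
#' Simulates (or loads) a cohort and produces per-participant and
#' group-level tables: per-band speech-brain MI for the story and
#' reversed-envelope surrogate conditions, within-channel cross-frequency
#' MI, lateralisation indices, edge list, PLV window statistics,
#' sampling-correlation summaries, complementarity summaries, and the group
#' randomisation statistics (story vs surrogate and LI vs 0, FDR
#' corrected). Every table carries the master seed, a config hash, and the
#' package version. With `cfg$out_dir` set, the tables are written as CSV
#' files plus a JSON run manifest.
#'
#' @param cfg a `run_config` from [default_config()] or [read_run_config()].
#' @return a named list of data frames (`mi`, `lateralisation`, `edges`,
#'   `plv`, `sampling`, `complementarity`, `group`), plus `cohort`.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- "setup"
  tables <- list()
  tryCatch({
    stage <- "cohort"
    cohort <- if (!is.null(cfg$input_dir)) load_cohort(cfg$input_dir)
              else cohort_from_config(cfg)
    env <- cohort$envelope
    n_bins <- cfg$mi$n_bins
    theta <- canonical_band("theta"); delta <- canonical_band("delta")
    gamma <- canonical_band("gamma")

    stage <- "envelope analytics"
    a_env <- list(delta = analytic(env, delta), theta = analytic(env, theta))
    rev_env <- surrogate_reversed(env)
    a_rev <- list(delta = analytic(rev_env, delta),
                  theta = analytic(rev_env, theta))

    stage <- "edges"
    edges <- do.call(detect_edges, c(list(env = env), cfg$edges))
    env_theta_ep <- if (nrow(edges) >= 2)
      epoch(a_env$theta, edges, cfg$epoch_window, "phase") else NULL

    stage <- "per-participant measures"
    mi_rows <- list(); li_rows <- list(); plv_rows <- list()
    samp_rows <- list(); comp_rows <- list()
    for (p in cohort$participants) {
      chans <- list(left = p$left, right = p$right)
      a_ch <- lapply(chans, function(ch)
        list(delta = analytic(ch, delta), theta = analytic(ch, theta),
             gamma = analytic(ch, gamma)))
      per_side <- list()
      for (side in names(chans)) {
        m <- list()
        for (bn in c("delta", "theta")) {
          m[[paste0(bn, "_pp")]] <- speech_brain_mi(
            a_env[[bn]], a_ch[[side]][[bn]], "phase-phase", n_bins)$mi
          m[[paste0(bn, "_pp_surr")]] <- speech_brain_mi(
            a_rev[[bn]], a_ch[[side]][[bn]], "phase-phase", n_bins)$mi
        }
        m$theta_gamma_pa <- speech_brain_mi(
          a_env$theta, a_ch[[side]]$gamma, "phase-amp", n_bins)$mi
        m$theta_gamma_pa_surr <- speech_brain_mi(
          a_rev$theta, a_ch[[side]]$gamma, "phase-amp", n_bins)$mi
        m$cfc_theta_gamma <- cross_frequency_mi(
          chans[[side]], theta, gamma, n_bins)$mi
        per_side[[side]] <- m
        mi_rows[[length(mi_rows) + 1L]] <- data.frame(
          participant = p$id, channel = side,
          as.data.frame(m, check.names = FALSE))

        if (isTRUE(cfg$complementarity$enable)) {
          keep <- trim_margin(length(env$x), env$fs, cfg$mi$discard)
          s_b <- equipopulated_bin(a_env$theta$phase[keep], n_bins)
          bp <- equipopulated_bin(a_ch[[side]]$theta$phase[keep], n_bins)
          ba <- equipopulated_bin(a_ch[[side]]$gamma$amplitude[keep], n_bins)
          cr <- complementarity(s_b, bp, ba,
                                n_shuffles = cfg$complementarity$n_shuffles,
                                seed = cfg$master_seed)
          comp_rows[[length(comp_rows) + 1L]] <- data.frame(
            participant = p$id, channel = side, delta_i = cr$delta_i,
            percent_gain = cr$percent_gain, p_value = cr$p_value)
        }
      }
      # bias-corrected MI can dip below zero for null couplings; the LI of a
      # non-negative quantity clamps such estimates at zero information
      li_of <- function(ms) lateralisation_index(max(per_side$left[[ms]], 0),
                                                 max(per_side$right[[ms]], 0))
      li_rows[[length(li_rows) + 1L]] <- data.frame(
        participant = p$id,
        li_theta_pp = li_of("theta_pp"),
        li_delta_pp = li_of("delta_pp"),
        li_cfc = li_of("cfc_theta_gamma"))

      if (!is.null(env_theta_ep)) {
        eps <- lapply(a_ch, function(a) epoch(a$theta, edges,
                                              cfg$epoch_window, "phase"))
        ws <- list(
          speech_left = window_stats(plv_speech_brain(eps$left, env_theta_ep),
                                     cfg$plv_windows),
          speech_right = window_stats(plv_speech_brain(eps$right, env_theta_ep),
                                      cfg$plv_windows),
          trials_left = window_stats(plv_across_trials(eps$left),
                                     cfg$plv_windows),
          trials_right = window_stats(plv_across_trials(eps$right),
                                      cfg$plv_windows),
          between = window_stats(plv_between_channels(eps$left, eps$right),
                                 cfg$plv_windows))
        for (v in names(ws)) {
          plv_rows[[length(plv_rows) + 1L]] <- data.frame(
            participant = p$id, variant = v, t(ws[[v]]))
        }
        if (isTRUE(cfg$sampling$enable) && nrow(edges) >= 10) {
          env_ep <- epoch(env, edges, cfg$epoch_window)
          for (side in names(chans)) {
            r_obs <- sampling_correlation(eps[[side]], env_ep, "phase",
                                          shuffle = FALSE,
                                          range = cfg$sampling$range,
                                          max_lag = cfg$sampling$max_lag)
            r_shuf <- sampling_correlation(eps[[side]], env_ep, "phase",
                                           shuffle = TRUE,
                                           seed = cfg$master_seed,
                                           range = cfg$sampling$range,
                                           max_lag = cfg$sampling$max_lag)
            samp_rows[[length(samp_rows) + 1L]] <- data.frame(
              participant = p$id, channel = side,
              mean_max_r = r_obs$mean_max_r,
              mean_max_r_shuffled = r_shuf$mean_max_r)
          }
        }
      }
    }
    tables$mi <- do.call(rbind, mi_rows)
    tables$lateralisation <- do.call(rbind, li_rows)
    tables$edges <- as.data.frame(edges)
    tables$plv <- if (length(plv_rows)) do.call(rbind, plv_rows) else NULL
    tables$sampling <- if (length(samp_rows)) do.call(rbind, samp_rows) else NULL
    tables$complementarity <- if (length(comp_rows)) do.call(rbind, comp_rows) else NULL

    stage <- "group statistics"
    g <- list()
    for (side in c("left", "right")) {
      sub <- tables$mi[tables$mi$channel == side, ]
      for (ms in c("delta_pp", "theta_pp", "theta_gamma_pa")) {
        d <- sub[[ms]] - sub[[paste0(ms, "_surr")]]
        rt <- randomisation_ttest(d, n_rand = cfg$stats$n_rand,
                                  seed = cfg$master_seed)
        g[[length(g) + 1L]] <- data.frame(
          measure = ms, channel = side, contrast = "story_vs_surrogate",
          mean_diff = mean(d), t = rt$t, p = rt$p)
      }
    }
    for (ms in c("li_theta_pp", "li_delta_pp", "li_cfc")) {
      rt <- randomisation_ttest(tables$lateralisation[[ms]],
                                n_rand = cfg$stats$n_rand,
                                seed = cfg$master_seed)
      g[[length(g) + 1L]] <- data.frame(
        measure = ms, channel = "both", contrast = "against_zero",
        mean_diff = mean(tables$lateralisation[[ms]]), t = rt$t, p = rt$p)
    }
    group <- do.call(rbind, g)
    group$significant_fdr <- fdr_correct(group$p, cfg$stats$q)
    tables$group <- group

    stage <- "provenance"
    h <- config_hash(cfg); v <- pkg_version()
    tables <- lapply(tables, function(tb) {
      if (is.null(tb) || nrow(tb) == 0) return(tb)
      tb$seed <- cfg$master_seed; tb$config_hash <- h; tb$version <- v
      tb
    })

    if (!is.null(cfg$out_dir)) {
      stage <- "writing outputs"
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      for (nm in names(tables)) {
        if (!is.null(tables[[nm]]))
          utils::write.csv(tables[[nm]],
                           file.path(cfg$out_dir, paste0(nm, ".csv")),
                           row.names = FALSE)
      }
      jsonlite::write_json(
        list(config_hash = h, version = v, master_seed = cfg$master_seed,
             tables = names(tables)),
        file.path(cfg$out_dir, "run_manifest.json"),
        auto_unbox = TRUE, pretty = TRUE)
    }
    c(tables, list(cohort = cohort))
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Coupling-depth recovery study
#'
#' Sweeps the injected coupling depth over a grid and, for each depth and
#' replicate seed, simulates an envelope plus one channel carrying theta
#' entrainment and theta-to-gamma nested coupling at that depth, then
#' measures theta phase-phase MI with the envelope and within-channel
#' theta-gamma MI. Reports per-depth means and the Spearman correlation of
#' the seed-averaged estimates with the true depth.
#'
#' @param cfg a `run_config`; `cfg$recovery` may override `depths`,
#'   `n_seeds`, `duration`.
#' @return list with `table` (depth x seed estimates), `summary` (per-depth
#'   means), `spearman_pp`, `spearman_cfc`.
#' @export
run_recovery_study <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  rc <- cfg$recovery
  depths <- if (!is.null(rc$depths)) rc$depths else c(0, 0.3, 0.6, 0.9)
  n_seeds <- if (!is.null(rc$n_seeds)) rc$n_seeds else 5
  duration <- if (!is.null(rc$duration)) rc$duration else 30
  theta <- canonical_band("theta"); gamma <- canonical_band("gamma")
  rows <- list()
  for (d in depths) {
    for (s in seq_len(n_seeds)) {
      seed <- cfg$master_seed + 1000L * s
      spec <- envelope_spec(duration, fs = cfg$simulation$fs, seed = seed)
      sim <- simulate_envelope(spec)
      cs <- coupling_spec(
        phase_entrainment = c(theta = d),
        nested_pac = if (d > 0)
          list(list(phase_band = theta, amp_freq = 40, depth = d)) else list(),
        snr = 1, seed = seed + 7L)
      ch <- simulate_channel(sim$envelope, sim$truth, cs)
      a_env <- analytic(sim$envelope, theta)
      a_ch <- analytic(ch, theta)
      rows[[length(rows) + 1L]] <- data.frame(
        depth = d, seed = seed,
        mi_pp = speech_brain_mi(a_env, a_ch, "phase-phase",
                                cfg$mi$n_bins)$mi,
        mi_cfc = cross_frequency_mi(ch, theta, gamma, cfg$mi$n_bins)$mi)
    }
  }
  tab <- do.call(rbind, rows)
  sm <- stats::aggregate(cbind(mi_pp, mi_cfc) ~ depth, tab, mean)
  list(table = tab, summary = sm,
       spearman_pp = stats::cor(sm$depth, sm$mi_pp, method = "spearman"),
       spearman_cfc = stats::cor(sm$depth, sm$mi_cfc, method = "spearman"))
}
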