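test_that("a step onset after silence is detected at the step", {
  fs <- 500
  x <- c(rep(0, round(0.5 * fs)), rep(1, round(1.2 * fs)))
  ed <- detect_edges(sampled_signal(x, fs))
  expect_equal(nrow(ed), 1)
  # the 20-ms mean-difference criterion first holds just before the step,
  # so the onset lands within one criterion half-window of the step
  step_i <- round(0.5 * fs) + 1
  expect_lte(ed$onset_index, step_i)
  expect_gte(ed$onset_index, step_i - round(0.02 * fs))
  expect_identical(ed$onset_index, oracle_edge_scan(x, fs))

  # constant envelope never satisfies the pre-onset silence criterion
  ed0 <- detect_edges(sampled_signal(rep(0.5, 3 * fs), fs))
  expect_equal(nrow(ed0), 0)

  expect_warning(z <- detect_edges(sampled_signal(rep(0, 3 * fs), fs)), "zero")
  expect_equal(nrow(z), 0)
})

test_that("detection agrees with the exhaustive per-sample criteria scan", {
  fs <- 250
  for (s in 1:6) {
    spec <- envelope_spec(16, fs = fs, n_bursts = 4, seed = s)
    sim <- simulate_envelope(spec)
    ed <- detect_edges(sim$envelope)
    oracle <- oracle_edge_scan(sim$envelope$x, fs)
    expect_identical(ed$onset_index, oracle)
  }
})

test_that("edge detection is invariant to envelope rescaling", {
  spec <- envelope_spec(20, n_bursts = 5, seed = 9)
  sim <- simulate_envelope(spec)
  e1 <- detect_edges(sim$envelope)
  e2 <- detect_edges(sampled_signal(7.3 * sim$envelope$x, sim$envelope$fs))
  expect_identical(e1$onset_index, e2$onset_index)
  expect_equal(e1$max_amp_200ms, e2$max_amp_200ms, tolerance = 1e-12)
})

test_that("epoching does index arithmetic and drops boundary onsets", {
  fs <- 1000
  x <- seq(0, 3, by = 1 / fs)   # ramp x(t) = t
  ep <- epoch(x, onsets = 1.0, window = c(-0.5, 1), fs = fs)
  expect_equal(dim(ep$data), c(1, 1501))
  expect_equal(ep$data[1, ], x[501:2001])
  expect_equal(ep$data[1, ], 1 + ep$times, tolerance = 1e-9)

  expect_message(ep2 <- epoch(x, onsets = c(0.1, 1.5), window = c(-0.5, 1), fs = fs),
                 "dropped")
  expect_equal(nrow(ep2$data), 1)
  expect_equal(ep2$n_dropped, 1)
  expect_error(epoch(x, onsets = 0.1, window = c(-0.5, 1), fs = fs), "usable")
})

test_that("PLV analytics match closed-form cases", {
  fs <- 100
  times <- seq(-0.2, 0.5, by = 1 / fs)
  mk_ep <- function(mat) structure(list(data = mat, times = times, fs = fs,
                                        window = range(times),
                                        onset_times = seq_len(nrow(mat)),
                                        n_dropped = 0L), class = "epoch_set")
  # identical phases: PLV 1 everywhere
  ph <- matrix(rep(runif(length(times), -pi, pi), 5), nrow = 5, byrow = TRUE)
  expect_equal(plv_across_trials(mk_ep(ph))$values,
               rep(1, length(times)), tolerance = 1e-12)
  # two antiphase trials: PLV 0
  ph2 <- rbind(rep(0.3, length(times)), rep(0.3 + pi, length(times)))
  expect_equal(max(plv_across_trials(mk_ep(ph2))$values), 0, tolerance = 1e-12)
  # common constant offset leaves PLV unchanged
  p1 <- plv_across_trials(mk_ep(ph2))$values
  p2 <- plv_across_trials(mk_ep(ph2 + 1.1))$values
  expect_equal(p1, p2, tolerance = 1e-12)
  # uniform random phases, n = 254: Rayleigh expectation sqrt(pi)/(2 sqrt(n))
  set.seed(6)
  mean_plv <- mean(replicate(50, {
    m <- matrix(runif(254 * length(times), -pi, pi), nrow = 254)
    mean(plv_across_trials(mk_ep(m))$values)
  }))
  expected <- sqrt(pi) / (2 * sqrt(254))
  expect_lt(abs(mean_plv - expected) / expected, 0.3)

  # speech-brain PLV: constant phase shift gives 1
  shift <- ph + 0.77
  expect_equal(plv_speech_brain(mk_ep(shift), mk_ep(ph))$values,
               rep(1, length(times)), tolerance = 1e-12)
  # between-channel PLV of a copy is 1
  expect_equal(plv_between_channels(mk_ep(ph), mk_ep(ph))$values,
               rep(1, length(times)), tolerance = 1e-12)
})

test_that("window statistics average the PLV series correctly", {
  times <- seq(-0.5, 1, by = 0.01)
  plv <- structure(list(values = rep(0.4, length(times)), times = times,
                        variant = "across_trials", n_trials = 10),
                   class = "plv_series")
  ws <- window_stats(plv)
  expect_equal(unname(ws), c(0.4, 0.4, 0.4))
  # step just after t = 0: baseline below early/late exactly by the step size
  plv$values <- ifelse(times <= 0, 0.2, 0.7)
  ws2 <- window_stats(plv)
  expect_equal(unname(ws2["early"] - ws2["baseline"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(ws2["late"] - ws2["baseline"]), 0.5, tolerance = 1e-9)
  expect_error(window_stats(plv, list(bad = c(5, 6))), "outside")
})

test_that("sampling correlation is perfect for constructed trials and drops under shuffling", {
  fs <- 200
  times <- seq(-0.5, 1, by = 1 / fs)
  n_tr <- 12
  set.seed(13)
  mk <- function(mat) structure(list(data = mat, times = times, fs = fs,
                                     window = c(-0.5, 1),
                                     onset_times = seq_len(nrow(mat)),
                                     n_dropped = 0L), class = "epoch_set")
  env <- matrix(rnorm(n_tr * length(times)), n_tr)
  env <- t(apply(env, 1, function(r) as.numeric(stats::filter(r, rep(1, 15),
                                                              sides = 2))))
  env[is.na(env)] <- 0
  # brain phase constructed so cos(phase) equals the envelope segment
  brain <- acos(pmin(pmax(env / max(abs(env)), -1), 1))
  r <- sampling_correlation(mk(brain), mk(env), mode = "phase")
  expect_equal(r$mean_max_r, 1, tolerance = 1e-6)
  r_sh <- sampling_correlation(mk(brain), mk(env), mode = "phase",
                               shuffle = TRUE, seed = 2)
  expect_lt(r_sh$mean_max_r, r$mean_max_r)
  # amplitude mode: identical trials give r = 1 as well
  ra <- sampling_correlation(mk(env), mk(env), mode = "amplitude")
  expect_equal(ra$mean_max_r, 1, tolerance = 1e-6)
})

test_that("circular-linear correlation recovers deterministic phase coding", {
  set.seed(14)
  amp <- runif(100, 0.3, 1)
  ph <- (0.4 + (pi / 2) * amp + pi) %% (2 * pi) - pi   # wrapped linear coding
  expect_gt(circ_lin_corr(ph, amp), 0.99)
  # independent phase: near chance
  expect_lt(circ_lin_corr(runif(100, -pi, pi), amp), 0.35)
})

test_that("phase coding of edge amplitude is significant only when present", {
  fs <- 200
  times <- seq(-0.5, 1, by = 1 / fs)
  mk <- function(mat) structure(list(data = mat, times = times, fs = fs,
                                     window = c(-0.5, 1),
                                     onset_times = seq_len(nrow(mat)),
                                     n_dropped = 0L), class = "epoch_set")
  set.seed(15)
  amp <- runif(40, 0.3, 1)
  coded <- vapply(amp, function(a) 0.2 + (pi / 2) * a + rnorm(1, 0, 0.1),
                  numeric(1))
  mat <- matrix(rep(coded, length(times)), nrow = 40)
  pc <- phase_amplitude_coding(mk(mat), amp, n_perm = 500, seed = 3)
  expect_gt(pc$r, 0.9)
  expect_lt(pc$p_value, 0.01)
  # no coding: p not small
  mat0 <- matrix(runif(40 * length(times), -pi, pi), nrow = 40)
  pc0 <- phase_amplitude_coding(mk(mat0), amp, n_perm = 500, seed = 4)
  expect_gt(pc0$p_value, 0.05)
})

test_that("edge-locked coupling contrast detects post-onset gating only", {
  fs <- 508
  times <- seq(-0.5, 0.5 - 1 / fs, by = 1 / fs)
  n_tr <- 60
  mk <- function(mat) structure(list(data = mat, times = times, fs = fs,
                                     window = c(-0.5, 0.5),
                                     onset_times = seq_len(nrow(mat)),
                                     n_dropped = 0L), class = "epoch_set")
  set.seed(16)
  build <- function(pac_pre, pac_post) {
    ph <- amp <- matrix(0, n_tr, length(times))
    for (tr in seq_len(n_tr)) {
      phase <- 2 * pi * 5 * times + runif(1, -pi, pi)
      ph[tr, ] <- atan2(sin(phase), cos(phase))
      depth <- ifelse(times < 0, pac_pre, pac_post)
      amp[tr, ] <- (1 + depth * cos(phase)) * (1 + 0.3 * rnorm(length(times)))
    }
    list(ph = mk(ph), amp = mk(amp))
  }
  gated <- build(0, 0.9)
  res <- edge_locked_pac(gated$ph, gated$amp)
  expect_gt(res$t, 2)
  expect_lt(res$p_value, 0.05)
  flat <- build(0.5, 0.5)
  res2 <- edge_locked_pac(flat$ph, flat$amp)
  expect_gt(res2$p_value, 0.05)
  none <- build(0, 0)
  res3 <- edge_locked_pac(none$ph, none$amp)
  expect_gt(res3$p_value, 0.05)
})

test_that("epoch-and-PLV pipeline is invariant to a common time shift", {
  fs <- 250
  spec <- envelope_spec(20, fs = fs, n_bursts = 5, seed = 21)
  sim <- simulate_envelope(spec)
  ch <- simulate_channel(sim$envelope, sim$truth,
                         coupling_spec(edge_reset = TRUE, reset_gain = 1,
                                       snr = 5, seed = 3))
  a <- analytic(ch, canonical_band("theta"))
  ed <- detect_edges(sim$envelope)
  p1 <- plv_across_trials(epoch(a, ed, c(-0.3, 0.6), "phase"))
  shift_n <- 100
  a2 <- a; a2$phase <- c(rep(a$phase[1], shift_n), a$phase)
  a2$amplitude <- c(rep(a$amplitude[1], shift_n), a$amplitude)
  p2 <- plv_across_trials(epoch(a2, ed$onset_time + shift_n / fs,
                                c(-0.3, 0.6)))
  expect_equal(p1$values, p2$values, tolerance = 1e-9)
})
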