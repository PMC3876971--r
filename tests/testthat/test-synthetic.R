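test_that("envelope generation is deterministic and satisfies its contract", {
  spec <- envelope_spec(20, n_bursts = 5, seed = 7)
  a <- simulate_envelope(spec)
  b <- simulate_envelope(spec)
  expect_identical(a$envelope$x, b$envelope$x)
  expect_identical(a$truth$edge_times, b$truth$edge_times)

  expect_true(all(a$envelope$x >= 0))
  expect_equal(length(a$truth$edge_times), 5)
  expect_true(all(diff(a$truth$edge_times) > 0))
  # normalised copy has max exactly 1
  expect_equal(max(a$envelope$x / max(a$envelope$x)), 1)
})

test_that("constructed edges are recovered at the truth times", {
  spec <- envelope_spec(25, n_bursts = 6, burst_amplitudes = c(0.5, 0.8, 1, 0.6, 0.9, 0.7),
                        seed = 2)
  sim <- simulate_envelope(spec)
  ed <- detect_edges(sim$envelope)
  expect_equal(nrow(ed), 6)
  expect_lte(max(abs(ed$onset_time - sim$truth$edge_times)),
             1 / sim$envelope$fs)

  # silence-only envelope yields no edges
  silent <- simulate_envelope(envelope_spec(5, n_bursts = 0, seed = 1))
  expect_equal(nrow(suppressWarnings(detect_edges(silent$envelope))), 0)
})

test_that("envelope power is concentrated at the modulation rates", {
  spec <- envelope_spec(40, n_bursts = 12, seed = 5)
  sim <- simulate_envelope(spec)
  x <- sim$envelope$x
  p_syll <- oracle_band_power(x, sim$envelope$fs, 3, 7)
  p_high <- oracle_band_power(x, sim$envelope$fs, 20, 30)
  expect_gt(p_syll / p_high, 10)
  p_low <- oracle_band_power(x, sim$envelope$fs, 0.2, 10)
  p_above <- oracle_band_power(x, sim$envelope$fs, 10, sim$envelope$fs / 2 - 1)
  expect_gt(p_low, p_above)
})

test_that("envelope_spec validates its invariants", {
  expect_error(envelope_spec(-1), "duration")
  expect_error(envelope_spec(10, fs = 8, syllable_rate = 4.5), "aliasing")
  expect_error(envelope_spec(10, n_bursts = 2, burst_amplitudes = c(1)), "length")
  expect_error(envelope_spec(10, n_bursts = 1, burst_amplitudes = 0.1), "exceed")
  expect_error(envelope_spec(5, n_bursts = 5), "too short")
})

test_that("null channels carry no detectable coupling", {
  spec <- envelope_spec(40, n_bursts = 12, seed = 3)
  sim <- simulate_envelope(spec)
  theta <- canonical_band("theta"); gamma <- canonical_band("gamma")
  a_env <- analytic(sim$envelope, theta)
  cs0 <- coupling_spec(snr = 1, seed = 17)
  ch0 <- simulate_channel(sim$envelope, sim$truth, cs0)
  # phase-phase MI against a small reversed-envelope surrogate distribution
  a_ch <- analytic(ch0, theta)
  mi_obs <- speech_brain_mi(a_env, a_ch, "phase-phase")$mi
  a_rev <- analytic(surrogate_reversed(sim$envelope), theta)
  mi_surr <- speech_brain_mi(a_rev, a_ch, "phase-phase")$mi
  expect_lt(mi_obs, abs(mi_surr) + 0.05)
  expect_lt(abs(cross_frequency_mi(ch0, theta, gamma)$mi), 0.02)
})

test_that("perfect theta entrainment locks the channel to the envelope phase", {
  spec <- envelope_spec(40, n_bursts = 12, seed = 3)
  sim <- simulate_envelope(spec)
  theta <- canonical_band("theta")
  ch <- simulate_channel(sim$envelope, sim$truth,
                         coupling_spec(phase_entrainment = c(theta = 1),
                                       snr = Inf, seed = 5))
  a_env <- analytic(sim$envelope, theta)
  a_ch <- analytic(ch, theta)
  keep <- trim_idx <- (2 * 1017):(38 * 1017)
  # phase comparison restricted to samples where the envelope's band phase is
  # defined (amplitude above its median); elsewhere phase is arbitrary
  sel <- keep[a_env$amplitude[keep] >= median(a_env$amplitude[keep])]
  plv <- Mod(mean(exp(1i * (a_env$phase[sel] - a_ch$phase[sel]))))
  expect_gt(plv, 0.99)
})

test_that("nested coupling strength is recovered monotonically", {
  theta <- canonical_band("theta"); gamma <- canonical_band("gamma")
  depths <- c(0, 0.3, 0.6, 0.9)
  n_seeds <- 6
  means <- sapply(depths, function(d) {
    mean(sapply(seq_len(n_seeds), function(s) {
      spec <- envelope_spec(25, n_bursts = 7, seed = s)
      sim <- simulate_envelope(spec)
      cs <- coupling_spec(nested_pac = if (d > 0)
        list(list(phase_band = theta, amp_freq = 40, depth = d)) else list(),
        snr = 1, seed = 100 + s)
      if (d == 0) cs$nested_pac <- list(list(phase_band = theta, amp_freq = 40,
                                             depth = 0))
      ch <- simulate_channel(sim$envelope, sim$truth, cs)
      cross_frequency_mi(ch, theta, gamma)$mi
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("cohorts are written per participant with a truth manifest", {
  d <- withr::local_tempdir()
  spec <- envelope_spec(8, n_bursts = 2, seed = 1)
  cs <- coupling_spec(snr = 1)
  out <- simulate_cohort(2, cs, cs, spec, master_seed = 4, out_dir = d)
  expect_setequal(basename(list.dirs(d, recursive = FALSE)), c("P01", "P02"))
  expect_true(file.exists(file.path(d, "truth.json")))
  man <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(man$n_participants, 2)
  expect_length(man$participant_seeds, 2)
  expect_match(man$generator, "synthetic")
  # round-trip of a channel file
  got <- read_signal_csv(file.path(d, "P01", "left.csv"))
  expect_equal(got$x, out$participants[[1]]$left$x, tolerance = 1e-12)
  # reproducibility under the same master seed
  out2 <- simulate_cohort(2, cs, cs, spec, master_seed = 4)
  expect_identical(out$participants[[2]]$right$x, out2$participants[[2]]$right$x)
})

test_that("coupling_spec rejects invalid strengths", {
  expect_error(coupling_spec(phase_entrainment = c(theta = 1.5)), "0, 1")
  expect_error(coupling_spec(phase_entrainment = c(1)), "named")
  expect_error(coupling_spec(snr = 0), "snr")
  expect_error(coupling_spec(speechphase_to_amp = -0.2), "0, 1")
})

test_that("1/f noise has a falling spectrum", {
  set.seed(8)
  x <- pink_noise(2^15, 1000)
  p_low <- oracle_band_power(x, 1000, 1, 10)
  p_high <- oracle_band_power(x, 1000, 100, 110)
  expect_gt(p_low / p_high, 5)
  expect_equal(sd(x), 1, tolerance = 1e-6)
})
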