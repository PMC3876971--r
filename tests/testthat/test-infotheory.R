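test_that("equipopulated binning yields equal counts and rank invariance", {
  b <- equipopulated_bin(0:999, 10)
  expect_true(all(table(b$labels) == 100))
  expect_equal(sort(unique(b$labels)), 1:10)

  # any strictly monotone transform gives identical labels
  set.seed(3)
  x <- rnorm(500)
  b1 <- equipopulated_bin(x, 10)
  b2 <- equipopulated_bin(exp(2 * x) + 5, 10)
  expect_identical(b1$labels, b2$labels)

  # uniform phases: bin boundaries near equal-width circular bins
  set.seed(4)
  ph <- runif(1000, -pi, pi)
  b3 <- equipopulated_bin(ph, 10)
  widths <- diff(b3$boundaries)
  expect_lt(max(abs(widths - 2 * pi / 10)) / (2 * pi / 10), 0.2)

  expect_warning(equipopulated_bin(rep(1, 50)), "constant")
  expect_error(equipopulated_bin(1:5, 10), "shorter")
})

test_that("plug-in MI matches the histogram formula on hand-specified tables", {
  # identical uniform 10-ary series: log2 10 bits
  lab <- rep(1:10, each = 1000)
  b <- binned_from_labels(lab, 10)
  expect_equal(mi_plugin(b, b)$mi, log2(10), tolerance = 1e-12)

  # exact product table: independence, 0 bits
  tab_ind <- outer(c(10, 20, 30, 40), c(5, 10, 15, 20))
  lt <- labels_from_table(tab_ind)
  expect_equal(mi_plugin(binned_from_labels(lt$x, 4),
                         binned_from_labels(lt$y, 4))$mi, 0, tolerance = 1e-12)

  # printed 2x2 table {{40,10},{10,40}} against the direct formula
  tab <- matrix(c(40, 10, 10, 40), 2, byrow = TRUE)
  lt <- labels_from_table(tab)
  expect_equal(mi_plugin(binned_from_labels(lt$x, 2),
                         binned_from_labels(lt$y, 2))$mi,
               oracle_mi_from_table(tab), tolerance = 1e-12)

  # random <= 5x5 tables agree with the oracle to 1e-12 bits
  set.seed(9)
  for (k in 1:20) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    tab <- matrix(rpois(nr * nc, 8) + 1, nr, nc)
    lt <- labels_from_table(tab)
    got <- mi_plugin(binned_from_labels(lt$x, nr), binned_from_labels(lt$y, nc))$mi
    expect_equal(got, oracle_mi_from_table(tab), tolerance = 1e-12)
  }
})

test_that("plug-in MI is symmetric, non-negative, and bounded by the entropies", {
  set.seed(12)
  for (k in 1:10) {
    bx <- equipopulated_bin(rnorm(400), sample(3:10, 1))
    by <- equipopulated_bin(rnorm(400), sample(3:10, 1))
    mxy <- mi_plugin(bx, by)$mi
    myx <- mi_plugin(by, bx)$mi
    expect_equal(mxy, myx, tolerance = 1e-12)
    expect_gte(mxy, 0)
    expect_lte(mxy, min(log2(bx$n_bins), log2(by$n_bins)) + 1e-12)
  }
})

test_that("quadratic extrapolation removes most of the small-sample bias", {
  # independent 10x10 at n = 1000: plug-in bias near the Miller-Madow
  # first-order prediction (9*9 / (2 n ln 2) = 0.0584 bits); the corrected
  # estimator is nearly unbiased
  set.seed(21)
  n_rep <- 60
  pl <- qe <- numeric(n_rep)
  for (k in seq_len(n_rep)) {
    bx <- equipopulated_bin(rnorm(1000), 10)
    by <- equipopulated_bin(rnorm(1000), 10)
    pl[k] <- mi_plugin(bx, by)$mi
    qe[k] <- mi_qe(bx, by)$mi
  }
  mm <- 81 / (2 * 1000 * log(2))
  expect_lt(abs(mean(pl) - mm) / mm, 0.2)
  expect_lt(abs(mean(qe)), 0.015)

  # bias scales ~1/N: doubling n roughly halves the plug-in bias
  set.seed(22)
  pl2 <- replicate(60, mi_plugin(equipopulated_bin(rnorm(2000), 10),
                                 equipopulated_bin(rnorm(2000), 10))$mi)
  expect_lt(abs(mean(pl2) / mean(pl) - 0.5), 0.3 * 0.5)
})

test_that("quadratic extrapolation leaves saturated dependence untouched", {
  set.seed(23)
  x <- rnorm(5000)
  bx <- equipopulated_bin(x, 10)
  est <- mi_qe(bx, bx)
  expect_equal(est$mi, log2(10), tolerance = 0.05)
  expect_equal(est$mi_plugin, log2(10), tolerance = 1e-12)
  expect_true(est$bias_corrected)
  # too short to split: falls back to plug-in with a warning
  expect_warning(short <- mi_qe(binned_from_labels(rep(1:2, 5), 10),
                                binned_from_labels(rep(1:2, 5), 10)),
                 "plug-in|plugin|short")
})

test_that("joint MI obeys monotonicity, redundancy and XOR synergy", {
  set.seed(31)
  for (k in 1:8) {
    bs <- equipopulated_bin(rnorm(600), 4)
    b1 <- equipopulated_bin(rnorm(600), 4)
    b2 <- equipopulated_bin(rnorm(600), 4)
    expect_gte(mi_joint(bs, b1, b2, method = "plugin")$mi,
               mi_plugin(bs, b1)$mi - 1e-12)
  }
  # constant or duplicate second response adds nothing (plug-in exact)
  bs <- equipopulated_bin(rnorm(600), 4)
  b1 <- equipopulated_bin(rnorm(600), 4)
  bconst <- binned_from_labels(rep(1L, 600), 1)
  expect_equal(mi_joint(bs, b1, bconst, method = "plugin")$mi,
               mi_plugin(bs, b1)$mi, tolerance = 1e-12)
  expect_equal(mi_joint(bs, b1, b1, method = "plugin")$mi,
               mi_plugin(bs, b1)$mi, tolerance = 1e-12)

  # XOR: marginals carry nothing, the pair carries the full bit
  reps <- 200
  y1 <- rep(c(0L, 0L, 1L, 1L), reps); y2 <- rep(c(0L, 1L, 0L, 1L), reps)
  s <- as.integer(xor(y1, y2))
  bs <- binned_from_labels(s + 1L, 2); by1 <- binned_from_labels(y1 + 1L, 2)
  by2 <- binned_from_labels(y2 + 1L, 2)
  expect_equal(mi_plugin(bs, by1)$mi, 0, tolerance = 1e-12)
  expect_equal(mi_plugin(bs, by2)$mi, 0, tolerance = 1e-12)
  expect_equal(mi_joint(bs, by1, by2, method = "plugin")$mi, 1, tolerance = 1e-12)
})

test_that("complementarity detects synergy and stays null for redundant or noise responses", {
  set.seed(41)
  n <- 5000
  # b_amp a deterministic relabelling of b_phase: exactly zero gain
  s <- equipopulated_bin(rnorm(n), 4)
  bp <- equipopulated_bin(rnorm(n), 4)
  ba_dup <- binned_from_labels(5L - bp$labels, 4)
  cr <- complementarity(s, bp, ba_dup, n_shuffles = 100, seed = 1)
  expect_equal(cr$i_joint$mi_plugin, cr$i_base$mi_plugin, tolerance = 1e-12)

  # constructed synergy: stimulus is a (phase-part, amp-part) pair
  sp <- sample(0:1, n, TRUE); sa <- sample(0:1, n, TRUE)
  s2 <- binned_from_labels(2L * sp + sa + 1L, 4)
  bp2 <- binned_from_labels(sp + 1L, 2)
  ba2 <- binned_from_labels(sa + 1L, 2)
  cr2 <- complementarity(s2, bp2, ba2, n_shuffles = 200, seed = 2)
  expect_lt(cr2$p_value, 0.05)
  expect_gt(cr2$delta_i, 0.5)

  # pure-noise amplitude: gain within the null spread
  ba3 <- equipopulated_bin(rnorm(n), 4)
  cr3 <- complementarity(s, bp, ba3, n_shuffles = 200, seed = 3)
  expect_gt(cr3$p_value, 0.05)
  null_delta <- cr3$null_distribution - cr3$i_base_plugin
  obs_delta <- cr3$i_joint_plugin - cr3$i_base_plugin
  expect_lt(obs_delta, quantile(null_delta, 0.99))
})
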