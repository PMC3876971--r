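# Independent oracles used across the suite. These are deliberately naive
# re-derivations (per-sample loops, direct formulas) kept separate from the
# package's vectorised implementations.

# MI in bits from a joint count table, straight from the histogram formula
oracle_mi_from_table <- function(counts) {
  p <- counts / sum(counts)
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  total
}

# expand a joint count table into paired label vectors
labels_from_table <- function(counts) {
  xs <- ys <- integer(0)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      k <- counts[i, j]
      if (k > 0) { xs <- c(xs, rep(i, k)); ys <- c(ys, rep(j, k)) }
    }
  }
  list(x = xs, y = ys)
}

binned_from_labels <- function(labels, n_bins) {
  structure(list(labels = as.integer(labels), n_bins = as.integer(n_bins),
                 boundaries = NULL), class = "binned_series")
}

# per-sample scan of the three edge criteria, with the refractory collapse,
# written as a plain loop over every sample
oracle_edge_scan <- function(x, fs, thr = 0.05, pre = 0.4, post = 1,
                             half = 0.02, refractory = 0.4) {
  x <- x / max(x)
  n <- length(x)
  n_pre <- round(pre * fs); n_post <- round(post * fs); n_half <- round(half * fs)
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (i <= n_pre || i + n_post - 1 > n) next
    c1 <- mean(x[(i - n_pre):(i - 1)]) < thr
    if (!c1) next
    c2 <- mean(x[i:(i + n_post - 1)]) > thr
    if (!c2) next
    c3 <- (mean(x[i:(i + n_half - 1)]) - mean(x[(i - n_half):(i - 1)])) > thr
    if (c3) hits <- c(hits, i)
  }
  accepted <- integer(0)
  last <- -Inf
  for (h in hits) {
    if (h - last > refractory * fs) { accepted <- c(accepted, h); last <- h }
  }
  accepted
}

# periodogram band power by direct DFT evaluation
oracle_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- abs(fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= lo & f <= hi
  sum(sp[sel])
}

# tiny PCM16 WAV writer for round-trip tests
write_test_wav <- function(path, x, fs, n_channels = 1) {
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(n_channels), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * n_channels * 2), con, size = 4, endian = "little")
  writeBin(as.integer(n_channels * 2), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
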