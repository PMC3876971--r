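#' Lateralisation index
#'
#' LI = (right - left) / (right + left) for a non-negative quantity measured
#' in homologous right and left channels. Positive values indicate right
#' dominance. Vectorised; cells with `left + right = 0` are returned as `NA`
#' with a message (the index is undefined there).
#'
#' @param left,right non-negative values (scalars or equal-length vectors).
#' @return LI in [-1, 1] (or `NA` where undefined).
#' @examples
#' lateralisation_index(left = 2, right = 1)  # -1/3
#' @export
lateralisation_index <- function(left, right) {
  if (length(left) != length(right)) stop("left/right length mismatch")
  if (any(left < 0 | right < 0)) stop("values must be non-negative")
  tot <- left + right
  bad <- tot == 0
  if (any(bad)) message(sum(bad), " cell(s) with left + right = 0 excluded")
  li <- ifelse(bad, NA_real_, (right - left) / tot)
  li
}

#' Randomisation dependent-samples t-test
#'
#' Observed dependent-samples t per cell, with a null distribution built by
#' random sign flips of the per-participant differences (the exchangeability
#' null for a paired design). Two-sided p-values use the (b + 1)/(n_rand + 1)
#' estimator so p is never exactly zero.
#'
#' @param diffs numeric vector (one cell) or participants x cells matrix of
#'   per-participant differences: condition differences for a paired
#'   contrast, or raw values for a test against zero.
#' @param n_rand number of randomisations (default 500).
#' @param seed RNG seed.
#' @return an object of class `stat_result`: `t`, `p` per cell, `n_rand`.
#' @export
randomisation_ttest <- function(diffs, n_rand = 500, seed = 1) {
  d <- if (is.matrix(diffs)) diffs else matrix(diffs, ncol = 1)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 participants")
  tstat <- function(m) {
    mu <- colMeans(m)
    se <- apply(m, 2, stats::sd) / sqrt(n)
    ifelse(se == 0, ifelse(mu == 0, 0, sign(mu) * Inf), mu / se)
  }
  t_obs <- tstat(d)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  exceed <- numeric(ncol(d))
  for (r in seq_len(n_rand)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    t_null <- tstat(d * flips)
    exceed <- exceed + (abs(t_null) >= abs(t_obs) - 1e-12)
  }
  p <- (exceed + 1) / (n_rand + 1)
  structure(list(t = t_obs, p = p, n_rand = n_rand), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %d cell(s), %d randomisations; min p = %.4g\n",
              length(x$t), x$n_rand, min(x$p)))
  invisible(x)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up false-discovery-rate control at level `q`; a thin wrapper around
#' `stats::p.adjust(method = "BH")` returning the significance mask.
#'
#' @param p vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return logical mask, TRUE where significant after correction.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Bootstrap percentile threshold of a group mean
#'
#' Draws participants with replacement `n_boot` times, computes the group
#' mean per cell in each draw, and returns the requested percentile of the
#' bootstrap distribution per cell.
#'
#' @param values numeric vector (one cell) or participants x cells matrix.
#' @param n_boot bootstrap iterations (default 500).
#' @param pct percentile (default 95).
#' @param seed RNG seed.
#' @return per-cell threshold (numeric vector).
#' @export
bootstrap_percentile <- function(values, n_boot = 500, pct = 95, seed = 1) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 participants")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  boots <- matrix(NA_real_, n_boot, ncol(v))
  for (b in seq_len(n_boot)) {
    boots[b, ] <- colMeans(v[sample(n, replace = TRUE), , drop = FALSE])
  }
  apply(boots, 2, stats::quantile, probs = pct / 100, names = FALSE)
}
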