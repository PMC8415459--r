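# Sloan neutral community model with a binomial (random-sampling) comparison,
# and niche-breadth / dispersal metrics.

#' Neutral-model occurrence prediction
#'
#' Probability that a taxon of mean relative abundance `p_bar` is detected
#' (local relative abundance above `d`) under Sloan's neutral model:
#' `1 - BetaCDF(d; N m p_bar, N m (1 - p_bar))`.
#'
#' @param p_bar mean relative abundance (vectorized)
#' @param m migration rate
#' @param N community size (reads)
#' @param d detection limit (relative abundance)
#' @export
sloan_occupancy <- function(p_bar, m, N, d = 1 / N) {
  stats::pbeta(d, N * m * p_bar, N * m * (1 - p_bar), lower.tail = FALSE)
}

#' Fit the Sloan migration parameter from summary statistics
#'
#' Least-squares fit of `m` given per-taxon mean relative abundances and
#' occurrence frequencies (the curve-level core of [fit_sloan()]).
#'
#' @param p_bar per-taxon mean relative abundance
#' @param f_obs per-taxon occurrence frequency
#' @param N community size (reads)
#' @param d detection limit
#' @return list: m, r_squared, f_pred
#' @export
fit_sloan_curve <- function(p_bar, f_obs, N, d = 1 / N) {
  sse <- function(m) sum((f_obs - sloan_occupancy(p_bar, m, N, d))^2)
  m_hat <- stats::optimize(sse, interval = c(1e-6, 1))$minimum
  f_hat <- sloan_occupancy(p_bar, m_hat, N, d)
  list(m = m_hat,
       r_squared = 1 - sum((f_obs - f_hat)^2) /
         sum((f_obs - mean(f_obs))^2),
       f_pred = f_hat)
}

#' Fit Sloan's neutral community model
#'
#' Fits the single migration parameter `m` by least squares between observed
#' occurrence frequencies and the beta-distribution prediction
#' `f_pred = 1 - BetaCDF(d; N m p, N m (1 - p))`, where `p` is a taxon's mean
#' relative abundance across local communities, `N` the mean reads per sample
#' and `d` the detection limit. Lower `m` indicates stronger dispersal
#' limitation.
#'
#' @param x an [otu_table()]
#' @param d detection limit as relative abundance; default `1/N` (one read at
#'   mean depth)
#' @return list of class `neutral_fit`: m, N, d, r_squared (generalized,
#'   `1 - SS_err / SS_total`), aic_neutral, aic_binomial, and a per-taxon
#'   data.frame (p_bar, f_obs, f_pred_neutral, f_pred_binomial, band relative
#'   to the neutral prediction).
#' @export
fit_sloan <- function(x, d = NULL) {
  cnt <- unclass(x)
  keep <- colSums(cnt) > 0
  cnt <- cnt[, keep, drop = FALSE]
  if (ncol(cnt) < 10) stop("need at least 10 taxa with reads")
  N <- mean(rowSums(cnt))
  if (is.null(d)) d <- 1 / N
  f <- sweep(cnt, 1, rowSums(cnt), "/")
  p_bar <- colMeans(f)
  f_obs <- colMeans(cnt > 0)
  crv <- fit_sloan_curve(p_bar, f_obs, N, d)
  m_hat <- crv$m
  f_hat <- crv$f_pred
  ss_err <- sum((f_obs - f_hat)^2)
  ss_tot <- sum((f_obs - mean(f_obs))^2)
  n <- length(f_obs)
  bin <- binomial_null_fit(x, d = d)
  taxa <- data.frame(taxon_id = colnames(cnt), p_bar = p_bar, f_obs = f_obs,
                     f_pred_neutral = f_hat,
                     f_pred_binomial = bin$f_pred,
                     band = ifelse(f_obs > f_hat + 0.05, "above",
                                   ifelse(f_obs < f_hat - 0.05, "below",
                                          "within")),
                     row.names = NULL)
  structure(list(m = m_hat, N = N, d = d,
                 r_squared = 1 - ss_err / ss_tot,
                 aic_neutral = n * log(ss_err / n) + 2 * 1,
                 aic_binomial = bin$aic,
                 taxa = taxa),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf(paste0("Sloan neutral model: m = %.4f, N = %.1f, d = %.2e\n",
                     "generalized R^2 = %.3f\nAIC neutral = %.2f, ",
                     "AIC binomial = %.2f (%s preferred)\n"),
              x$m, x$N, x$d, x$r_squared, x$aic_neutral, x$aic_binomial,
              if (x$aic_neutral < x$aic_binomial) "neutral" else "binomial"))
  invisible(x)
}

#' Binomial (random-sampling) occurrence model
#'
#' Occurrence probability of each taxon if local communities were random
#' `N`-read draws from the metacommunity (no dispersal limitation or drift):
#' `f_pred = 1 - BinomCDF(ceil(d N) - 1; N, p_bar)`. No free parameters.
#'
#' @inheritParams fit_sloan
#' @return list: `f_pred` per taxon and least-squares `aic` (k = 0)
#' @export
binomial_null_fit <- function(x, d = NULL) {
  cnt <- unclass(x)
  cnt <- cnt[, colSums(cnt) > 0, drop = FALSE]
  N <- mean(rowSums(cnt))
  if (is.null(d)) d <- 1 / N
  Ni <- max(1L, round(N))
  f <- sweep(cnt, 1, rowSums(cnt), "/")
  p_bar <- colMeans(f)
  f_obs <- colMeans(cnt > 0)
  f_pred <- stats::pbinom(ceiling(d * Ni) - 1, Ni, p_bar, lower.tail = FALSE)
  ss_err <- sum((f_obs - f_pred)^2)
  n <- length(f_obs)
  list(f_pred = f_pred, aic = n * log(ss_err / n),
       r_squared = 1 - ss_err / sum((f_obs - mean(f_obs))^2))
}

#' Levins niche breadth of one taxon
#'
#' `B = 1 / sum_i P_i^2` where `P_i` is the share of the taxon's reads found
#' in sample `i`; ranges from 1 (single sample) to the number of samples
#' (perfectly even).
#'
#' @param taxon_counts counts of one taxon across samples
#' @export
levins_b <- function(taxon_counts) {
  tot <- sum(taxon_counts)
  if (tot <= 0) stop("taxon absent from all samples")
  p <- taxon_counts / tot
  1 / sum(p^2)
}

#' Community niche breadth per sample
#'
#' Unweighted mean of Levins B over the taxa present (count > 0) in each
#' sample. An abundance-weighted variant is available via `weighted = TRUE`.
#'
#' @param x an [otu_table()]
#' @param weighted weight the mean by within-sample relative abundance
#' @return named numeric vector of Bcom per sample
#' @export
community_niche_breadth <- function(x, weighted = FALSE) {
  cnt <- unclass(x)
  if (any(rowSums(cnt) == 0)) stop("empty sample")
  B <- apply(cnt, 2, levins_b)
  out <- numeric(nrow(cnt))
  for (i in seq_len(nrow(cnt))) {
    pres <- cnt[i, ] > 0
    out[i] <- if (weighted)
      sum(B[pres] * cnt[i, pres]) / sum(cnt[i, pres])
    else mean(B[pres])
  }
  stats::setNames(out, rownames(cnt))
}

#' Community-level dispersal ability
#'
#' For each sample pair the shared proportion is the mean, over the two
#' samples, of the summed relative abundance of taxa present in both;
#' `D` is the average over all pairs. `D = 1` iff all samples share identical
#' support. A conservative min-of-two-sides variant is available.
#'
#' @param x an [otu_table()]
#' @param side `"mean"` (default) or `"min"` of the two per-sample shares
#' @return list: `pairs` data.frame (sample_i, sample_j, shared_proportion)
#'   and scalar `D`
#' @export
dispersal_ability <- function(x, side = c("mean", "min")) {
  side <- match.arg(side)
  f <- to_relative_abundance(x)
  n <- nrow(f)
  if (n < 2) stop("need at least two samples")
  res <- data.frame()
  pres <- f > 0
  s <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      shared <- pres[i, ] & pres[j, ]
      a <- sum(f[i, shared])
      b <- sum(f[j, shared])
      s[i, j] <- if (side == "mean") 0.5 * (a + b) else min(a, b)
    }
  ut <- which(upper.tri(s), arr.ind = TRUE)
  pairs <- data.frame(sample_i = rownames(f)[ut[, 1]],
                      sample_j = rownames(f)[ut[, 2]],
                      shared_proportion = s[ut])
  list(pairs = pairs, D = mean(pairs$shared_proportion))
}
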