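# Threshold indicator taxa analysis: per-taxon change points along an
# environmental gradient scored by group-equalized indicator values (IndVal),
# permutation z-scores and bootstrap purity/reliability; community-level
# thresholds as sums of filtered z-scores by direction.

#' Candidate change points along a gradient
#'
#' Unique sorted gradient values that leave at least `min_side` samples on
#' each side of the split (left group: gradient <= value).
#'
#' @param gradient numeric gradient values, one per sample
#' @param min_side minimum group size on each side
#' @export
candidate_change_points <- function(gradient, min_side = 5) {
  n <- length(gradient)
  if (n < 2 * min_side) stop("too few samples for min_side")
  u <- sort(unique(gradient))
  left <- vapply(u, function(v) sum(gradient <= v), numeric(1))
  out <- u[left >= min_side & (n - left) >= min_side]
  if (!length(out)) stop("no valid candidate change points")
  out
}

# IndVal (Dufrene-Legendre, group-equalized, on relative abundance means and
# occurrence frequencies, scaled to [0, 100]) at every candidate split.
# Returns per-candidate IndVal of the larger side and its direction.
indval_curve <- function(abundance, gradient, candidates) {
  ord <- order(gradient)
  a <- abundance[ord]
  x <- gradient[ord]
  n <- length(a)
  csum <- cumsum(a)
  cocc <- cumsum(a > 0)
  tot <- csum[n]
  occ <- cocc[n]
  k <- findInterval(candidates, x) # samples with gradient <= candidate
  mean_l <- csum[k] / k
  mean_r <- (tot - csum[k]) / (n - k)
  denom <- mean_l + mean_r
  A_l <- ifelse(denom > 0, mean_l / denom, 0)
  A_r <- ifelse(denom > 0, mean_r / denom, 0)
  iv_l <- 100 * A_l * (cocc[k] / k)
  iv_r <- 100 * A_r * ((occ - cocc[k]) / (n - k))
  data.frame(candidate = candidates,
             indval = pmax(iv_l, iv_r),
             direction = ifelse(iv_r >= iv_l, "z+", "z-"))
}

# hot path of the permutation/bootstrap loops: no data.frame allocation
max_indval <- function(abundance, gradient, candidates) {
  ord <- order(gradient)
  a <- abundance[ord]
  x <- gradient[ord]
  n <- length(a)
  csum <- cumsum(a)
  cocc <- cumsum(a > 0)
  tot <- csum[n]
  occ <- cocc[n]
  k <- findInterval(candidates, x)
  mean_l <- csum[k] / k
  mean_r <- (tot - csum[k]) / (n - k)
  denom <- mean_l + mean_r
  sel <- denom > 0
  iv_l <- iv_r <- numeric(length(k))
  iv_l[sel] <- 100 * (mean_l[sel] / denom[sel]) * (cocc[k][sel] / k[sel])
  iv_r[sel] <- 100 * (mean_r[sel] / denom[sel]) *
    ((occ - cocc[k][sel]) / (n - k[sel]))
  iv <- pmax(iv_l, iv_r)
  i <- which.max(iv)
  list(indval = iv[i], cp = candidates[i],
       direction = if (iv_r[i] >= iv_l[i]) "z+" else "z-")
}

#' TITAN analysis of one taxon
#'
#' The observed statistic is the maximum IndVal over candidate change points;
#' its z-score comes from gradient permutations of the same statistic.
#' Bootstrap resampling of samples yields purity (share of bootstraps
#' agreeing in direction) and reliability (share with permutation p <= 0.05).
#' A taxon passes the filter when purity and reliability both reach 0.95.
#'
#' @param abundance counts of the taxon across samples
#' @param gradient environmental gradient values
#' @param n_perm permutations for the z-score / p-value
#' @param n_boot bootstrap replicates (0 skips the bootstrap; purity and
#'   reliability are then `NA` and the taxon is never flagged as filtered)
#' @param seed optional integer seed; `NULL` continues the current RNG stream
#' @param min_side minimum group size per side of a split
#' @param boot_n_perm permutations inside each bootstrap (default `n_perm`)
#' @return one-row data.frame: change_point, direction, indval, z, p, purity,
#'   reliability, filtered
#' @export
taxon_titan <- function(abundance, gradient, n_perm = 250, n_boot = 500,
                        seed = NULL, min_side = 5, boot_n_perm = n_perm) {
  if (sum(abundance > 0) < 3) stop("taxon present in fewer than 3 samples")
  if (!is.null(seed)) set.seed(seed)
  candidates <- candidate_change_points(gradient, min_side)
  obs <- max_indval(abundance, gradient, candidates)
  null_max <- vapply(seq_len(n_perm), function(r)
    max_indval(sample(abundance), gradient, candidates)$indval, numeric(1))
  sd_null <- stats::sd(null_max)
  if (sd_null < 1e-12) {
    warning("degenerate permutation null: z undefined")
    z <- NA_real_
  } else z <- (obs$indval - mean(null_max)) / sd_null
  p <- (1 + sum(null_max >= obs$indval)) / (1 + n_perm)
  agree <- 0L
  reliable <- 0L
  n <- length(gradient)
  if (n_boot == 0) {
    return(data.frame(change_point = obs$cp, direction = obs$direction,
                      indval = obs$indval, z = z, p = p,
                      purity = NA_real_, reliability = NA_real_,
                      filtered = FALSE))
  }
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    gb <- gradient[idx]
    ab <- abundance[idx]
    cb <- tryCatch(candidate_change_points(gb, min_side),
                   error = function(e) NULL)
    if (is.null(cb) || sum(ab > 0) < 3) next
    ob <- max_indval(ab, gb, cb)
    if (ob$direction == obs$direction) agree <- agree + 1L
    nb <- vapply(seq_len(boot_n_perm), function(r)
      max_indval(sample(ab), gb, cb)$indval, numeric(1))
    pb <- (1 + sum(nb >= ob$indval)) / (1 + boot_n_perm)
    if (pb <= 0.05) reliable <- reliable + 1L
  }
  purity <- agree / n_boot
  reliability <- reliable / n_boot
  data.frame(change_point = obs$cp, direction = obs$direction,
             indval = obs$indval, z = z, p = p,
             purity = purity, reliability = reliability,
             filtered = !is.na(z) & purity >= 0.95 & reliability >= 0.95)
}

#' Community-level thresholds from filtered TITAN taxa
#'
#' Tallies the z-scores of filtered taxa at their observed change points,
#' separately for decreasers (z-) and increasers (z+); the community
#' thresholds are the candidates where sum(z-) and sum(z+) peak. Also reports
#' the change-point density across candidates.
#'
#' @param taxon_results data.frame of per-taxon results (rows as returned by
#'   [taxon_titan()], with a `taxon_id` column)
#' @param candidates candidate change points of the gradient
#' @return list: `curve` data.frame (candidate, sum_z_minus, sum_z_plus,
#'   density), `peak_z_minus`, `peak_z_plus` (NA when no taxa of that
#'   direction survive the filter)
#' @export
community_thresholds <- function(taxon_results, candidates) {
  fl <- taxon_results[taxon_results$filtered & !is.na(taxon_results$z), ,
                      drop = FALSE]
  if (nrow(fl) == 0) {
    warning("no filtered taxa")
    return(list(curve = data.frame(candidate = candidates, sum_z_minus = 0,
                                   sum_z_plus = 0, density = 0),
                peak_z_minus = NA_real_, peak_z_plus = NA_real_))
  }
  nearest <- vapply(fl$change_point, function(cp)
    candidates[which.min(abs(candidates - cp))], numeric(1))
  sum_zm <- vapply(candidates, function(cp)
    sum(fl$z[fl$direction == "z-" & nearest == cp]), numeric(1))
  sum_zp <- vapply(candidates, function(cp)
    sum(fl$z[fl$direction == "z+" & nearest == cp]), numeric(1))
  dens <- vapply(candidates, function(cp) sum(nearest == cp), numeric(1)) /
    nrow(fl)
  list(curve = data.frame(candidate = candidates, sum_z_minus = sum_zm,
                          sum_z_plus = sum_zp, density = dens),
       peak_z_minus = if (any(sum_zm > 0)) candidates[which.max(sum_zm)]
                      else NA_real_,
       peak_z_plus = if (any(sum_zp > 0)) candidates[which.max(sum_zp)]
                     else NA_real_)
}

#' TITAN over all taxa of a table
#'
#' Runs [taxon_titan()] for every taxon present in at least `min_occ` samples
#' and summarizes community thresholds.
#'
#' @param x an [otu_table()]
#' @param gradient gradient value per sample (aligned with rows of `x`)
#' @param min_occ minimum occupancy for a taxon to be tested
#' @inheritParams taxon_titan
#' @return list: `taxa` data.frame, `community` ([community_thresholds()]
#'   output), `candidates`
#' @export
titan <- function(x, gradient, n_perm = 250, n_boot = 500, seed = 1,
                  min_side = 5, min_occ = 3) {
  stopifnot(length(gradient) == nrow(x))
  candidates <- candidate_change_points(gradient, min_side)
  cnt <- unclass(x)
  test <- colnames(cnt)[colSums(cnt > 0) >= min_occ]
  rows <- lapply(seq_along(test), function(i) {
    r <- tryCatch(
      taxon_titan(cnt[, test[i]], gradient, n_perm = n_perm,
                  n_boot = n_boot, seed = seed + i, min_side = min_side),
      warning = function(w) NULL)
    if (!is.null(r)) cbind(taxon_id = test[i], r)
  })
  taxa <- do.call(rbind, rows)
  list(taxa = taxa,
       community = community_thresholds(taxa, candidates),
       candidates = candidates)
}
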