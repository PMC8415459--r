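# Null-model partitioning of community assembly processes: beta-MNTD / beta-NTI
# against a tip-shuffling phylogenetic null, Raup-Crick on Bray-Curtis against
# a richness- and abundance-preserving taxonomic null, five-way classification
# of community pairs, and selection/dispersal summary ratios.

#' Abundance-weighted beta mean nearest taxon distance for one pair
#'
#' `0.5 * (sum_k f_ik min_l d(k, l) + sum_l f_jl min_k d(l, k))` where the
#' minima run over taxa present in the other community; a taxon present in
#' both contributes zero through its own term.
#'
#' @param relabund_i,relabund_j named relative-abundance vectors
#' @param taxon_distances symmetric cophenetic distance matrix covering all
#'   present taxa
#' @export
beta_mntd <- function(relabund_i, relabund_j, taxon_distances) {
  pi <- names(relabund_i)[relabund_i > 0]
  pj <- names(relabund_j)[relabund_j > 0]
  if (length(pi) == 0 || length(pj) == 0) stop("empty community")
  miss <- setdiff(c(pi, pj), rownames(taxon_distances))
  if (length(miss)) stop("taxa missing from distance matrix: ",
                         paste(miss, collapse = ", "))
  mn_i <- apply(taxon_distances[pj, pi, drop = FALSE], 2, min)
  mn_j <- apply(taxon_distances[pi, pj, drop = FALSE], 2, min)
  0.5 * (sum(relabund_i[pi] * mn_i) + sum(relabund_j[pj] * mn_j))
}

align_tree_distances <- function(x, tree) {
  taxa <- colnames(x)
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) stop("taxa not on tree: ", paste(miss, collapse = ", "))
  D <- stats::cophenetic(tree)
  D[taxa, taxa, drop = FALSE]
}

#' Beta nearest taxon index (beta-NTI) for all sample pairs
#'
#' The phylogenetic null shuffles taxon labels across the tips of the whole
#' tree and recomputes abundance-weighted beta-MNTD;
#' `beta-NTI = (obs - mean_null) / sd_null`. Pairs whose null distribution has
#' (numerically) zero spread are flagged degenerate and reported as `NA`.
#'
#' @param x an [otu_table()] or relative-abundance matrix
#' @param tree [ape::phylo] tree containing all taxa of `x`
#' @param n_null number of null randomizations (>= 2)
#' @param seed integer seed
#' @return list: `pairs` data.frame (sample_i, sample_j, bmntd, bnti,
#'   degenerate), plus `bmntd` and `bnti` matrices.
#' @export
bnti <- function(x, tree, n_null = 999, seed = 1) {
  if (n_null < 2) stop("n_null must be >= 2")
  F <- if (inherits(x, "otu_table")) to_relative_abundance(x) else unclass(x)
  D <- align_tree_distances(F, tree)
  set.seed(seed)
  res <- cpp_bnti_null(F, D, as.integer(n_null))
  sd0 <- res$null_sd < 1e-12
  bn <- (res$obs - res$null_mean) / res$null_sd
  bn[sd0] <- NA_real_
  dimnames(res$obs) <- dimnames(bn) <- list(rownames(F), rownames(F))
  ut <- which(upper.tri(bn), arr.ind = TRUE)
  pairs <- data.frame(sample_i = rownames(F)[ut[, 1]],
                      sample_j = rownames(F)[ut[, 2]],
                      bmntd = res$obs[ut],
                      bnti = bn[ut],
                      degenerate = sd0[ut])
  list(pairs = pairs, bmntd = res$obs, bnti = bn)
}

#' Raup-Crick (Bray-Curtis) for all sample pairs
#'
#' Null communities preserve each sample's observed richness (taxa drawn
#' without replacement with probability proportional to occurrence frequency
#' across samples) and total reads (one read per drawn taxon, the remainder
#' multinomial proportional to metacommunity relative abundance).
#' `RC = 2 [(#null < obs) + 0.5 (#null = obs)] / n_null - 1`, in `[-1, 1]`.
#'
#' @param x an [otu_table()]
#' @param n_null number of null replicates
#' @param seed integer seed
#' @return list: `pairs` data.frame (sample_i, sample_j, rc_bray) and the
#'   `rc` matrix.
#' @export
raup_crick_bray <- function(x, n_null = 999, seed = 1) {
  if (nrow(x) < 2) stop("need at least two samples")
  m <- unclass(x)
  storage.mode(m) <- "integer"
  set.seed(seed)
  rc <- cpp_rc_bray(m, as.integer(n_null))
  dimnames(rc) <- list(rownames(x), rownames(x))
  ut <- which(upper.tri(rc), arr.ind = TRUE)
  pairs <- data.frame(sample_i = rownames(x)[ut[, 1]],
                      sample_j = rownames(x)[ut[, 2]],
                      rc_bray = rc[ut])
  list(pairs = pairs, rc = rc)
}

#' Classify a community pair into an assembly process
#'
#' `beta-NTI > 2` variable selection; `< -2` homogeneous selection; otherwise
#' (or when the beta-NTI null is degenerate) `RC > 0.95` dispersal limitation,
#' `RC < -0.95` homogenizing dispersal, else undominated. Vectorized.
#'
#' @param bnti beta-NTI values (may contain `NA` for degenerate pairs)
#' @param rc Raup-Crick values; required for pairs not decided by beta-NTI
#' @param degenerate logical flag(s) for degenerate beta-NTI nulls
#' @return character vector of process labels
#' @export
classify_pair <- function(bnti, rc = NULL, degenerate = FALSE) {
  n <- length(bnti)
  degenerate <- rep_len(degenerate, n) | is.na(bnti)
  need_rc <- degenerate | abs(bnti) <= 2
  if (any(need_rc) && (is.null(rc) || any(is.na(rc[need_rc]))))
    stop("RC values required for pairs with |beta-NTI| <= 2 or degenerate null")
  lab <- character(n)
  sel <- !degenerate & bnti > 2
  hom <- !degenerate & bnti < -2
  lab[sel] <- "variable_selection"
  lab[hom] <- "homogeneous_selection"
  rest <- !(sel | hom)
  if (any(rest)) {
    lab[rest & rc > 0.95] <- "dispersal_limitation"
    lab[rest & rc < -0.95] <- "homogenizing_dispersal"
    lab[rest & abs(rc) <= 0.95] <- "undominated"
  }
  lab
}

PROCESS_LEVELS <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

#' Summarize assembly-process fractions and selection/dispersal ratios
#'
#' @param labels process labels from [classify_pair()]
#' @param vpa optional [variation_partition()] result, used for the
#'   VPA-based selection/dispersal ratio (pure environmental over pure spatial
#'   adjusted R^2)
#' @param rc optional vector of Raup-Crick values from the taxonomic-only
#'   analysis; reported as the fraction of pairs with `|RC| > 0.95`
#' @return list: `fractions` (named, sums to 1), `sder_null` (`Inf` flagged
#'   via `sder_null_defined = FALSE` when the dispersal fraction is 0, `NaN`
#'   when both are 0), `sder_vpa`, `stochastic_fraction_rc`,
#'   `rc_within_null_fraction` (share with `|RC| <= 0.95`), `n_pairs`.
#' @export
process_summary <- function(labels, vpa = NULL, rc = NULL) {
  if (length(labels) < 1) stop("no classified pairs")
  fr <- prop.table(table(factor(labels, levels = PROCESS_LEVELS)))
  fr <- stats::setNames(as.numeric(fr), PROCESS_LEVELS)
  sel <- fr[["variable_selection"]] + fr[["homogeneous_selection"]]
  disp <- fr[["dispersal_limitation"]]
  sder <- if (disp > 0) sel / disp else if (sel > 0) Inf else NaN
  out <- list(fractions = fr, sder_null = sder,
              sder_null_defined = disp > 0, n_pairs = length(labels))
  if (!is.null(vpa)) {
    pure_env <- vpa$fractions[["pure_soil"]] + vpa$fractions[["pure_climate"]] +
      vpa$fractions[["overlap_soil_climate"]]
    pure_space <- vpa$fractions[["pure_space"]]
    out$sder_vpa <- if (pure_space > 0) pure_env / pure_space else Inf
  }
  if (!is.null(rc)) {
    rc <- rc[!is.na(rc)]
    out$stochastic_fraction_rc <- mean(abs(rc) > 0.95)
    out$rc_within_null_fraction <- mean(abs(rc) <= 0.95)
  }
  out
}

#' Phylogenetic-signal pretest
#'
#' Per-taxon niche values are abundance-weighted means of each (standardized)
#' environmental variable; the Euclidean between-taxon niche distances are
#' related to cophenetic distances by a Mantel correlogram. Significant
#' positive correlation at the shortest distance classes indicates the
#' phylogenetic signal required for beta-NTI.
#'
#' @param x an [otu_table()]
#' @param tree [ape::phylo] tree containing the taxa of `x`
#' @param metadata sample metadata with the variables in `vars`
#' @param vars environmental variable names
#' @param n_classes distance classes (`NULL` = Sturges)
#' @param n_perm permutations per class
#' @return list: `correlogram` data.frame, `niche` matrix (taxa x vars),
#'   `signal` (TRUE when the shortest class has positive r with Holm p < 0.05)
#' @export
phylo_signal <- function(x, tree, metadata, vars, n_classes = NULL,
                         n_perm = 999) {
  E <- as.matrix(metadata[, vars, drop = FALSE])
  if (any(apply(E, 2, stats::sd) == 0))
    stop("constant environmental variable")
  E <- scale(E)
  cnt <- unclass(x)
  niche <- t(cnt) %*% E / colSums(cnt)
  rownames(niche) <- colnames(x)
  nd <- as.matrix(stats::dist(niche))
  if (all(nd == 0)) stop("zero niche distances")
  cd <- align_tree_distances(x, tree)
  cg <- mantel_correlogram(nd, cd, n_classes = n_classes, n_perm = n_perm)
  list(correlogram = cg, niche = niche,
       signal = nrow(cg) > 0 && !is.na(cg$r[1]) && cg$r[1] > 0 &&
         !is.na(cg$p_holm[1]) && cg$p_holm[1] < 0.05)
}

complete_submatrix <- function(m) {
  # drop samples greedily until no missing pairs remain
  while (anyNA(m[upper.tri(m)])) {
    na_count <- rowSums(is.na(m) & upper.tri(m, diag = FALSE) |
                          is.na(m) & lower.tri(m, diag = FALSE))
    drop <- which.max(na_count)
    m <- m[-drop, -drop, drop = FALSE]
  }
  m
}

#' Rank environmental drivers of beta-NTI variation
#'
#' Mantel tests of the pairwise (signed) beta-NTI matrix against the Euclidean
#' distance matrix of each variable; the best variable is re-tested by a
#' partial Mantel controlling for geographic distance and all other variables,
#' and visualized as a Mantel correlogram. Degenerate pairs are removed by
#' dropping samples until the beta-NTI matrix is complete.
#'
#' @param bnti_matrix square matrix of pairwise beta-NTI values (NA allowed)
#' @param metadata sample metadata (rows aligned with the matrix)
#' @param geo geographic distance matrix
#' @param vars environmental variable names
#' @param n_perm permutations
#' @return list: `ranking` data.frame (variable, r, p), `best`, `partial`
#'   (partial Mantel for the best variable), `correlogram`
#' @export
bnti_env_drivers <- function(bnti_matrix, metadata, geo, vars,
                             n_perm = 999) {
  m <- complete_submatrix(as.matrix(bnti_matrix))
  if (nrow(m) < 4) stop("too few non-degenerate pairs")
  if (stats::sd(m[lower.tri(m)]) == 0) stop("constant beta-NTI matrix")
  keep <- match(rownames(m), rownames(as.matrix(geo)))
  g <- as.matrix(geo)[keep, keep]
  md <- metadata[keep, , drop = FALSE]
  env_dist <- lapply(vars, function(v)
    as.matrix(stats::dist(scale(md[[v]]))))
  names(env_dist) <- vars
  rk <- do.call(rbind, lapply(vars, function(v) {
    mt <- mantel(m, env_dist[[v]], n_perm = n_perm,
                 alternative = "two.sided")
    data.frame(variable = v, r = mt$r, p = mt$p)
  }))
  rk <- rk[order(-abs(rk$r)), ]
  best <- rk$variable[1]
  controls <- c(list(g), env_dist[setdiff(vars, best)])
  pm <- do.call(partial_mantel,
                c(list(m, env_dist[[best]]), controls,
                  list(n_perm = n_perm, alternative = "two.sided")))
  cg <- mantel_correlogram(m, env_dist[[best]], n_perm = n_perm)
  list(ranking = rk, best = best, partial = pm, correlogram = cg)
}

#' Full null-model assembly analysis
#'
#' Runs [bnti()] and [raup_crick_bray()], classifies every pair and summarizes
#' process fractions.
#'
#' @inheritParams bnti
#' @param vpa optional [variation_partition()] result forwarded to
#'   [process_summary()]
#' @return list: `pairs` (PairAssembly data.frame with process labels),
#'   `summary` ([process_summary()] output), `bnti`, `rc` matrices.
#' @export
assembly_processes <- function(x, tree, n_null = 999, seed = 1, vpa = NULL) {
  bn <- bnti(x, tree, n_null = n_null, seed = seed)
  rc <- raup_crick_bray(x, n_null = n_null, seed = seed + 1)
  pairs <- merge(bn$pairs, rc$pairs, by = c("sample_i", "sample_j"))
  pairs$process <- classify_pair(pairs$bnti, pairs$rc_bray, pairs$degenerate)
  list(pairs = pairs,
       summary = process_summary(pairs$process, vpa = vpa,
                                 rc = pairs$rc_bray),
       bnti = bn$bnti, rc = rc$rc)
}
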