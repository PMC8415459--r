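# Co-occurrence network inference: Spearman + Bray-Curtis similarity edge
# scores, permutation/bootstrap (ReBoot-style) p-values with compositional
# renormalization, Brown's combination of the two measures, BH correction,
# random-matrix-theory selection of the correlation threshold, module
# detection, eigengenes, and per-sample local networks.

#' Pairwise taxon association scores
#'
#' Spearman correlation (mid-ranked ties) and Bray-Curtis similarity
#' (1 - dissimilarity) between the abundance profiles of every taxon pair
#' across samples. Constant taxa yield `NA` correlations.
#'
#' @param relabund samples x taxa relative-abundance matrix
#' @return list: `rho` and `bc_sim` taxa x taxa matrices
#' @export
pairwise_scores <- function(relabund) {
  m <- unclass(relabund)
  if (nrow(m) < 4) stop("need at least 4 samples")
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  const <- apply(m, 2, function(z) stats::sd(z) == 0)
  rho[const, ] <- NA
  rho[, const] <- NA
  bc <- 1 - as.matrix(vegan::vegdist(t(m), method = "bray"))
  diag(rho) <- 1
  diag(bc) <- 1
  list(rho = rho, bc_sim = bc)
}

pair_scores_once <- function(a, b) {
  c(spearman = suppressWarnings(stats::cor(a, b, method = "spearman")),
    bc_sim = 1 - sum(abs(a - b)) / sum(a + b))
}

#' ReBoot-style permutation/bootstrap p-values for one taxon pair
#'
#' Permutation null: one taxon's values are shuffled across samples and every
#' sample's composition renormalized (easing compositional bias) before the
#' scores are recomputed; the null value is the mean of this distribution.
#' Bootstrap: samples are resampled with replacement to give a score
#' distribution with mean `mu_b` and sd `sigma_b`. The two-sided p-value is
#' the Gaussian tail probability of the null value under `N(mu_b, sigma_b)`.
#'
#' @param relabund samples x taxa relative-abundance matrix (rows sum to 1)
#' @param pair length-2 vector of taxon names or column indices
#' @param n_perm permutations
#' @param n_boot bootstrap replicates
#' @param seed optional integer seed (`NULL` continues the RNG stream)
#' @return list: `p` (named: spearman, bc_sim), `scores` (observed),
#'   `degenerate` (TRUE where `sigma_b` was 0 and p was set to 1)
#' @export
reboot_pvalues <- function(relabund, pair, n_perm = 1000, n_boot = 1000,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- unclass(relabund)
  a <- m[, pair[1]]
  b <- m[, pair[2]]
  obs <- pair_scores_once(a, b)
  if (anyNA(obs))
    return(list(p = c(spearman = 1, bc_sim = 1), scores = obs,
                degenerate = TRUE))
  n <- length(a)
  null_scores <- matrix(NA_real_, n_perm, 2)
  for (k in seq_len(n_perm)) {
    ap <- sample(a)
    s <- 1 - a + ap # new row totals after swapping the permuted column in
    null_scores[k, ] <- pair_scores_once(ap / s, b / s)
  }
  boot_scores <- matrix(NA_real_, n_boot, 2)
  for (k in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    boot_scores[k, ] <- pair_scores_once(a[idx], b[idx])
  }
  mu_null <- colMeans(null_scores, na.rm = TRUE)
  mu_b <- colMeans(boot_scores, na.rm = TRUE)
  sd_b <- apply(boot_scores, 2, stats::sd, na.rm = TRUE)
  degen <- !is.finite(sd_b) | sd_b < 1e-12
  p <- numeric(2)
  for (j in 1:2) {
    if (degen[j]) p[j] <- 1
    else {
      tail <- stats::pnorm(mu_null[j], mu_b[j], sd_b[j])
      p[j] <- min(1, 2 * min(tail, 1 - tail))
    }
  }
  list(p = stats::setNames(p, c("spearman", "bc_sim")), scores = obs,
       degenerate = any(degen))
}

#' Combine two dependent p-values by Brown's method
#'
#' `X = -2 (ln p1 + ln p2)` is referred to a scaled chi-square `c chi^2(f)`
#' with `c = Var(X) / (2 E[X])` and `f = 2 E[X]^2 / Var(X)` (the
#' moment-matched effective degrees of freedom), where `E[X] = 4` and
#' `Var(X) = 8 + 2 cov`. At zero covariance this is Fisher's method
#' (`chi^2` on 4 df).
#'
#' @param p1,p2 p-values in (0, 1] (vectorized)
#' @param cov_estimate covariance of the paired `-2 ln p` values (e.g. from
#'   [estimate_brown_cov()])
#' @export
browns_combine <- function(p1, p2, cov_estimate = 0) {
  if (any(p1 <= 0) || any(p2 <= 0)) stop("p-values must be positive")
  x <- -2 * (log(p1) + log(p2))
  e <- 4
  # the moment-matched variance must stay positive; an empirical covariance
  # below -4 (possible with degenerate p's) is truncated
  v <- max(8 + 2 * cov_estimate, 1e-3)
  cc <- v / (2 * e)
  f <- 2 * e^2 / v
  stats::pchisq(x / cc, df = f, lower.tail = FALSE)
}

#' Empirical covariance of paired -2 ln p values across candidate edges
#'
#' @param p1,p2 vectors of p-values over the candidate edge set
#' @export
estimate_brown_cov <- function(p1, p2) {
  if (length(p1) < 3) return(0)
  stats::cov(-2 * log(p1), -2 * log(p2))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, via [stats::p.adjust()].
#'
#' @param p_values vector of p-values
#' @export
bh_adjust <- function(p_values) stats::p.adjust(p_values, method = "BH")

nnsd_poisson_p <- function(rho, threshold, min_component = 20,
                           n_bins = 20) {
  A <- (abs(rho) >= threshold) * 1
  A[is.na(A)] <- 0
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  if (comp$csize[big] < min_component) return(NA_real_)
  idx <- which(comp$membership == big)
  ev <- eigen(A[idx, idx], symmetric = TRUE, only.values = TRUE)$values
  tryCatch({
    dens <- stats::density(ev)
    dx <- diff(dens$x[1:2])
    cdf <- cumsum(dens$y) * dx
    cdf <- cdf / max(cdf)
    u <- length(ev) * stats::approx(dens$x, cdf, sort(ev), rule = 2)$y
    s <- diff(u)
    s <- s[s >= 0]
    s <- s / mean(s)
    edges <- seq(0, 3, length.out = n_bins + 1)
    obs <- graphics::hist(s[s < 3], breaks = edges, plot = FALSE)$counts
    expd <- length(s) * (exp(-edges[-length(edges)]) - exp(-edges[-1]))
    keep <- expd > 1e-8
    chi2 <- sum((obs[keep] - expd[keep])^2 / expd[keep])
    stats::pchisq(chi2, df = sum(keep) - 1, lower.tail = FALSE)
  }, error = function(e) NA_real_)
}

#' Random-matrix-theory correlation threshold
#'
#' Scans |rho| thresholds; at each, the nearest-neighbor spacing distribution
#' of the unfolded adjacency spectrum (largest connected component) is tested
#' against the Poisson (exponential) law by a chi-square statistic. Returns
#' the lowest threshold at which Poisson statistics fit (p > 0.05) and keep
#' fitting at all higher scanned thresholds - the GOE-to-Poisson transition.
#'
#' @param rho taxa x taxa Spearman correlation matrix (>= 30 taxa)
#' @param scan thresholds to scan
#' @param min_component minimum size of the largest component for a spectrum
#'   to be evaluated
#' @param fallback value returned (with a warning) when no scanned threshold
#'   qualifies; defaults to the highest scanned threshold
#' @return list: `threshold`, `scan` data.frame (threshold, poisson_p)
#' @export
rmt_threshold <- function(rho, scan = seq(0.5, 0.95, by = 0.01),
                          min_component = 20, fallback = NULL) {
  if (ncol(rho) < 30) stop("need at least 30 taxa")
  ps <- vapply(scan, function(t)
    nnsd_poisson_p(rho, t, min_component), numeric(1))
  tab <- data.frame(threshold = scan, poisson_p = ps)
  usable <- which(!is.na(ps))
  chosen <- NA_real_
  for (i in usable) {
    later <- usable[usable >= i]
    if (all(ps[later] > 0.05)) { chosen <- scan[i]; break }
  }
  if (is.na(chosen)) {
    chosen <- if (is.null(fallback)) max(scan) else fallback
    warning("no threshold passed the Poisson fit; falling back to ", chosen)
  }
  list(threshold = chosen, scan = tab)
}

#' Score, test and assemble the co-occurrence edge table
#'
#' Computes pairwise scores, selects candidate edges at `|rho| >= rho_min`
#' (from [rmt_threshold()] when not supplied), computes ReBoot p-values for
#' both measures, combines them by Brown's method with the empirical
#' covariance, and BH-adjusts.
#'
#' @param x an [otu_table()] (apply [filter_rare_relative()] beforehand for
#'   the metacommunity network)
#' @param rho_min correlation threshold; `NULL` runs [rmt_threshold()]
#' @param n_perm,n_boot ReBoot replicates per edge
#' @param seed integer seed
#' @return list: `edges` data.frame (taxon_1, taxon_2, rho, bc_sim,
#'   p_spearman, p_bc, brown_p, q, sign, kept), `rho_min`, `scores`
#' @export
score_edges <- function(x, rho_min = NULL, n_perm = 1000, n_boot = 1000,
                        seed = 1) {
  f <- to_relative_abundance(x)
  sc <- pairwise_scores(f)
  if (is.null(rho_min)) rho_min <- rmt_threshold(sc$rho)$threshold
  ut <- which(upper.tri(sc$rho) & abs(sc$rho) >= rho_min, arr.ind = TRUE)
  if (nrow(ut) == 0) stop("no candidate edges at |rho| >= ", rho_min)
  set.seed(seed)
  res <- lapply(seq_len(nrow(ut)), function(k)
    reboot_pvalues(f, c(ut[k, 1], ut[k, 2]), n_perm = n_perm,
                   n_boot = n_boot))
  p1 <- vapply(res, function(r) max(r$p[["spearman"]], 1e-300), numeric(1))
  p2 <- vapply(res, function(r) max(r$p[["bc_sim"]], 1e-300), numeric(1))
  brown <- browns_combine(p1, p2, estimate_brown_cov(p1, p2))
  edges <- data.frame(taxon_1 = colnames(f)[ut[, 1]],
                      taxon_2 = colnames(f)[ut[, 2]],
                      rho = sc$rho[ut], bc_sim = sc$bc_sim[ut],
                      p_spearman = p1, p_bc = p2,
                      brown_p = brown, q = bh_adjust(brown),
                      sign = ifelse(sc$rho[ut] >= 0, "+", "-"))
  list(edges = edges, rho_min = rho_min, scores = sc)
}

#' Build the signed co-occurrence graph
#'
#' Keeps edges with `q <= q_max` and `|rho| >= rho_min`; returns an undirected
#' [igraph] graph with `sign` and `rho` edge attributes and a `domain` node
#' attribute.
#'
#' @param edges edge data.frame from [score_edges()]
#' @param q_max BH-adjusted p-value cutoff
#' @param rho_min correlation threshold
#' @param domains optional named character vector of per-taxon domain tags
#' @export
build_network <- function(edges, q_max = 0.05, rho_min = 0, domains = NULL) {
  keep <- edges$q <= q_max & abs(edges$rho) >= rho_min
  if (!any(keep)) stop("no edges pass the filters")
  el <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    el[, c("taxon_1", "taxon_2", "rho", "sign")], directed = FALSE)
  if (!is.null(domains))
    igraph::V(g)$domain <- unname(domains[igraph::V(g)$name])
  g
}

#' Extract the subgraph of one domain
#'
#' Nodes of the given domain and the edges with both endpoints in it.
#'
#' @param graph an igraph graph with a `domain` vertex attribute
#' @param domain `"bacteria"` or `"fungi"`
#' @export
domain_subgraph <- function(graph, domain) {
  igraph::induced_subgraph(graph,
                           which(igraph::V(graph)$domain == domain))
}

positive_subgraph <- function(graph) {
  if (!is.null(igraph::E(graph)$rho))
    igraph::subgraph_from_edges(graph, which(igraph::E(graph)$rho > 0),
                                delete.vertices = FALSE)
  else graph
}

#' Fast-greedy module detection
#'
#' CNM agglomerative modularity maximization ([igraph::cluster_fast_greedy()])
#' on the positive-edge subgraph (negative edges are retained in the graph but
#' excluded from clustering, which requires non-negative weights). Dominant
#' modules hold more than 10% of the nodes.
#'
#' @param graph an igraph graph (edge attribute `rho` marks signs; absent =
#'   all positive)
#' @param weighted use `rho` as edge weights (default unweighted)
#' @return list: `membership` (named), `modularity`, `sizes`,
#'   `dominant` (module ids holding > 10% of nodes)
#' @export
fast_greedy_modules <- function(graph, weighted = FALSE) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  gp <- positive_subgraph(graph)
  w <- if (weighted) igraph::E(gp)$rho else NULL
  cl <- igraph::cluster_fast_greedy(gp, weights = w)
  memb <- igraph::membership(cl)
  # the all-in-one partition (Q = 0) is always on the CNM merge path, so a
  # returned partition with negative Q collapses to a single module
  if (igraph::modularity(gp, memb, weights = w) < 0)
    memb[] <- 1
  sizes <- table(memb)
  list(membership = memb,
       modularity = igraph::modularity(gp, memb, weights = w),
       sizes = as.numeric(sizes),
       dominant = as.integer(names(sizes)[sizes >
                                            0.1 * igraph::vcount(graph)]))
}

#' Module eigengene
#'
#' First principal component of the standardized (z-scored per taxon) member
#' abundances across samples, with the sign fixed so the eigengene correlates
#' positively with the mean standardized member abundance. Optionally
#' correlates the eigengene with environmental variables (Spearman).
#'
#' @param relabund samples x taxa relative-abundance matrix
#' @param members taxon names of the module (>= 3)
#' @param metadata optional sample metadata
#' @param vars variable names for the environmental correlation
#' @return list: `eigengene` (per sample), `variance_explained` (fraction),
#'   `env_cor` (named Spearman correlations, when metadata given)
#' @export
module_eigengene <- function(relabund, members, metadata = NULL,
                             vars = NULL) {
  if (length(members) < 3) stop("module must have at least 3 taxa")
  Z <- scale(unclass(relabund)[, members, drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  eig <- pc$x[, 1]
  if (stats::cor(eig, rowMeans(Z)) < 0) eig <- -eig
  out <- list(eigengene = eig,
              variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
  if (!is.null(metadata)) {
    if (is.null(vars)) vars <- setdiff(colnames(metadata), "sample_id")
    out$env_cor <- vapply(vars, function(v)
      suppressWarnings(stats::cor(eig, metadata[[v]], method = "spearman")),
      numeric(1))
  }
  out
}

local_graph_features <- function(g) {
  gp <- positive_subgraph(g)
  memb <- if (igraph::ecount(gp) > 0)
    igraph::membership(igraph::cluster_fast_greedy(gp)) else NULL
  c(density = igraph::edge_density(g),
    clustering = {
      tr <- igraph::transitivity(g, type = "global")
      if (is.nan(tr)) 0 else tr
    },
    mean_degree = mean(igraph::degree(g)),
    mean_closeness = {
      cl <- suppressWarnings(igraph::closeness(g))
      mean(cl[is.finite(cl)], na.rm = TRUE)
    },
    mean_eigencent = mean(igraph::eigen_centrality(g)$vector),
    modularity = if (is.null(memb)) 0
                 else igraph::modularity(gp, memb),
    diameter = igraph::diameter(g),
    avg_path = igraph::mean_distance(g),
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g))
}

#' Per-sample local co-occurrence networks
#'
#' Induces, for every sample, the subgraph of the metacommunity network on the
#' taxa present (count > 0) in that sample and computes graph-level features:
#' density, global clustering coefficient, mean degree/closeness/eigenvector
#' centrality, fast-greedy modularity, diameter, average shortest path length,
#' node and edge counts.
#'
#' @param graph metacommunity igraph graph
#' @param x the [otu_table()] the graph was inferred from
#' @return data.frame of features, one row per sample
#' @export
local_networks <- function(graph, x) {
  cnt <- unclass(x)
  feats <- lapply(rownames(cnt), function(s) {
    present <- colnames(cnt)[cnt[s, ] > 0]
    nodes <- intersect(present, igraph::V(graph)$name)
    if (length(nodes) < 2)
      stop("sample ", s, " retains fewer than 2 network nodes")
    local_graph_features(igraph::induced_subgraph(graph, nodes))
  })
  out <- as.data.frame(do.call(rbind, feats))
  rownames(out) <- rownames(cnt)
  out
}

#' Distance matrix of local-network topology
#'
#' Drops features with pairwise |Spearman rho| > 0.7 across samples,
#' standardizes the rest, and returns the Euclidean distance between samples.
#'
#' @param features data.frame from [local_networks()]
#' @param rho_max collinearity cutoff
#' @return list: `dist` (sample distance matrix), `kept` feature names
#' @export
local_feature_distance <- function(features, rho_max = 0.7) {
  keep <- drop_collinear(features,
                         colnames(features)[apply(features, 2,
                                                  stats::sd) > 0],
                         rho_max = rho_max)
  Z <- scale(as.matrix(features[, keep, drop = FALSE]))
  list(dist = stats::dist(Z), kept = keep)
}

#' Spatial variation of co-occurrence patterns
#'
#' OLS slope of the local-network feature distance against geographic
#' distance, plus a two-stage MRM on geographic and environmental distance
#' matrices.
#'
#' @param feature_dist sample distance matrix of network features
#' @param geo_dist geographic distance matrix (km)
#' @param env_dists named list of environmental distance matrices
#' @param n_perm MRM permutations
#' @return list: `slope`, `intercept`, `r_squared` of the OLS; `mrm`
#'   ([mrm_two_stage()] output)
#' @export
topology_vs_space <- function(feature_dist, geo_dist, env_dists = list(),
                              n_perm = 999) {
  f <- as.matrix(feature_dist)
  g <- as.matrix(geo_dist)
  y <- f[lower.tri(f)]
  x <- g[lower.tri(g)]
  fit <- stats::lm(y ~ x)
  preds <- c(list(geo = g), env_dists)
  m <- if (stats::sd(y) > 0)
    do.call(mrm_two_stage, c(list(feature_dist), preds,
                             list(n_perm = n_perm)))
  else {
    warning("constant network-feature distances; MRM skipped")
    NULL
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared, mrm = m)
}

#' Degree distribution export for scale-free inspection
#'
#' Log-log rank/degree table and the OLS slope of log frequency vs log degree
#' (reported descriptively; no distributional claim).
#'
#' @param graph an igraph graph
#' @export
degree_distribution_table <- function(graph) {
  deg <- igraph::degree(graph)
  tab <- table(deg[deg > 0])
  df <- data.frame(degree = as.numeric(names(tab)),
                   frequency = as.numeric(tab))
  slope <- if (nrow(df) >= 3)
    unname(stats::coef(stats::lm(log(frequency) ~ log(degree),
                                 data = df))[2])
  else NA_real_
  list(table = df, loglog_slope = slope)
}
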