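# Synthetic metacommunity generator. Every downstream stage is validated
# against communities whose assembly regime (neutral drift with migration,
# environmental selection, dispersal limitation, or a mixture) is known by
# construction, together with a phylogeny with tunable trait conservatism and
# spatially structured sites.

EDAPHIC_PANEL <- data.frame(
  name = c("pH", "OM", "TN", "TP", "TK", "AN", "AP", "AK", "Cl", "AB", "AS",
           "ECa", "EMg", "ACu", "AZn", "AFe", "AMn", "SC"),
  mean = c(6, 35, 1.5, 0.9, 12, 120, 30, 180, 25, 0.6, 30,
           8, 2, 1.2, 2.5, 100, 25, 150),
  sd = c(0.8, 12, 0.6, 0.35, 4, 45, 15, 70, 10, 0.25, 12,
         3, 0.8, 0.5, 1.1, 50, 10, 60),
  stringsAsFactors = FALSE)

#' Simulation configuration
#'
#' Bundles the parameters of the metacommunity generator. Defaults emulate a
#' regional rhizosphere survey scaled to desk size: 78 sites spanning ~650 km,
#' lognormal regional abundances, six measured edaphic variables.
#'
#' @param n_sites number of local communities (sites)
#' @param n_taxa regional species pool size
#' @param reads_per_sample sequencing depth per site
#' @param regime one of `"neutral"`, `"selection"`, `"dispersal_limited"`,
#'   `"mixed"`
#' @param m migration rate in (0, 1]: probability that a dead individual is
#'   replaced from the regional pool rather than locally. Default is
#'   regime-specific: 0.25 (a well-dispersed, bacteria-like community) for the
#'   neutral, selection and mixed regimes, 0.014 (a dispersal-limited,
#'   fungi-like community) for the dispersal-limited regime
#' @param niche_strength sigma of the Gaussian niche filter (standardized
#'   environmental units); larger = weaker selection
#' @param trait_conservatism lambda in `[0, 1]` blending Brownian-motion trait
#'   evolution (1 = fully conserved) with independent noise (0)
#' @param dispersal_decay kappa >= 0 of the exponential dispersal kernel
#'   (units of 1 / max-distance); 0 = complete homogenization
#' @param n_env number of edaphic variables generated
#' @param extent_km box diagonal of the sampled region
#' @param spatial_autocorr in `[0, 1]`: share of environmental variance tied
#'   to a spatially autocorrelated Gaussian field
#' @param seed integer seed (mandatory for reproducibility)
#' @export
simulation_config <- function(n_sites = 78, n_taxa = 1000,
                              reads_per_sample = 2000,
                              regime = c("neutral", "selection",
                                         "dispersal_limited", "mixed"),
                              m = NULL, niche_strength = 1,
                              trait_conservatism = 1, dispersal_decay = 20,
                              n_env = 6, extent_km = 650,
                              spatial_autocorr = 0.5, seed = 1) {
  regime <- match.arg(regime)
  if (is.null(m)) m <- if (regime == "dispersal_limited") 0.014 else 0.25
  stopifnot(n_sites >= 3, n_taxa >= 2, reads_per_sample >= 1,
            m > 0, m <= 1, niche_strength >= 0,
            trait_conservatism >= 0, trait_conservatism <= 1,
            dispersal_decay >= 0, spatial_autocorr >= 0,
            spatial_autocorr <= 1)
  structure(list(n_sites = n_sites, n_taxa = n_taxa,
                 reads_per_sample = reads_per_sample, regime = regime,
                 m = m, niche_strength = niche_strength,
                 trait_conservatism = trait_conservatism,
                 dispersal_decay = dispersal_decay, n_env = n_env,
                 extent_km = extent_km, spatial_autocorr = spatial_autocorr,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Yule tree with `n_taxa` tips, rescaled to total depth 1 and tips labeled
#' `t1..tn`.
#'
#' @param n_taxa number of tips (>= 2)
#' @param seed integer seed
#' @return an [ape::phylo] ultrametric tree
#' @export
simulate_tree <- function(n_taxa, seed) {
  if (n_taxa < 2) stop("need at least 2 taxa")
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}

#' Simulate spatially structured sites with environmental gradients
#'
#' Coordinates are drawn uniformly in a box whose diagonal is `extent_km`.
#' Each environmental variable mixes a spatially autocorrelated Gaussian field
#' (squared-exponential kernel on great-circle distances, range = extent / 3)
#' with independent noise; `spatial_autocorr` = 0 decouples environment from
#' space, values near 1 confound them.
#'
#' @param n_sites number of sites (>= 3)
#' @param extent_km region diagonal in km
#' @param n_env number of edaphic variables (named from a standard soil panel)
#' @param spatial_autocorr in `[0, 1]`
#' @param seed integer seed
#' @return data.frame: sample_id, latitude, longitude, elevation, MAT, MAP,
#'   plus `n_env` edaphic columns.
#' @export
simulate_sites <- function(n_sites, extent_km = 650, n_env = 6,
                           spatial_autocorr = 0.5, seed = 1) {
  if (n_sites < 3) stop("need at least 3 sites")
  n_env <- min(n_env, nrow(EDAPHIC_PANEL))
  set.seed(seed)
  side_km <- extent_km / sqrt(2)
  lat0 <- 24
  lat <- lat0 + stats::runif(n_sites, 0, side_km / 111.19)
  lon <- 103 + stats::runif(n_sites, 0, side_km /
                              (111.19 * cos(lat0 * pi / 180)))
  ids <- sprintf("S%03d", seq_len(n_sites))
  md <- data.frame(sample_id = ids, latitude = lat, longitude = lon)
  d <- as.matrix(geo_distance(md))
  ell <- extent_km / 3
  K <- exp(-(d / ell)^2 / 2) + diag(1e-6, n_sites)
  L <- chol(K)
  field <- function() drop(crossprod(L, stats::rnorm(n_sites)))
  a <- spatial_autocorr
  mix <- function() sqrt(a) * field() + sqrt(1 - a) * stats::rnorm(n_sites)
  md$elevation <- pmax(0, 1500 + 350 * mix())
  md$MAT <- 18 - 0.005 * (md$elevation - 1500) + 0.8 * mix()
  md$MAP <- pmax(300, 1100 + 180 * mix())
  for (v in seq_len(n_env)) {
    md[[EDAPHIC_PANEL$name[v]]] <-
      EDAPHIC_PANEL$mean[v] + EDAPHIC_PANEL$sd[v] * mix()
  }
  md
}

#' Assign phylogenetically conserved niche optima
#'
#' Brownian-motion evolution along the tree blended with independent noise:
#' `trait = sqrt(lambda) * BM + sqrt(1 - lambda) * iid`, each component
#' standardized, so `lambda = 1` gives fully conserved traits (positive
#' phylogenetic signal) and `lambda = 0` none.
#'
#' @param tree an [ape::phylo] tree
#' @param lambda conservatism in `[0, 1]`
#' @param n_vars number of trait columns
#' @param seed integer seed
#' @return matrix taxa x variables with tip labels as row names
#' @export
assign_conserved_traits <- function(tree, lambda, n_vars = 1, seed = 1) {
  stopifnot(lambda >= 0, lambda <= 1)
  set.seed(seed)
  S <- length(tree$tip.label)
  out <- matrix(NA_real_, S, n_vars,
                dimnames = list(tree$tip.label, paste0("trait", seq_len(n_vars))))
  for (v in seq_len(n_vars)) {
    bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    bm <- if (stats::sd(bm) > 0) (bm - mean(bm)) / stats::sd(bm) else bm * 0
    out[, v] <- sqrt(lambda) * bm + sqrt(1 - lambda) * stats::rnorm(S)
  }
  out
}

#' Sample one local community under Hubbell-type neutral drift
#'
#' Initializes by a multinomial draw from the regional pool `gamma`, then runs
#' `sweeps * reads` death-replacement events in which the replacement comes
#' from the pool with probability `m` and from the local community otherwise.
#'
#' @param gamma regional relative abundances (normalized internally)
#' @param reads community size (reads)
#' @param m migration rate in (0, 1]
#' @param seed optional integer seed; `NULL` continues the current RNG stream
#' @param sweeps number of full community turnovers (default 10)
#' @return integer count vector summing to `reads`
#' @export
sample_neutral_community <- function(gamma, reads, m, seed = NULL,
                                     sweeps = 10) {
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  cpp_neutral_drift(as.numeric(gamma), as.integer(reads), m,
                    as.integer(sweeps))
}

#' Simulate a metacommunity under a known assembly regime
#'
#' Generates the OTU table plus a ground-truth object. Regimes:
#' \describe{
#'   \item{neutral}{independent Hubbell drift at every site with migration m.}
#'   \item{selection}{the regional pool is filtered at each site by a Gaussian
#'     niche weight `exp(-(env - optimum)^2 / (2 sigma^2))` per (standardized)
#'     environmental variable, then sampled multinomially.}
#'   \item{dispersal_limited}{drift communities are blended across sites by an
#'     exponential distance kernel `exp(-kappa d / d_max)`; kappa = 0 fully
#'     homogenizes, large kappa preserves local drift divergence and induces
#'     distance decay.}
#'   \item{mixed}{selection weights applied to the dispersal-limited mixtures.}
#' }
#'
#' @param config a [simulation_config()]
#' @param tree optional tree (default: [simulate_tree()] at the config seed)
#' @param sites optional metadata (default: [simulate_sites()])
#' @return list with `table` ([otu_table()]), `tree`, `sites`, and `truth`
#'   (gamma, optima, regime, parameters).
#' @export
simulate_regime <- function(config, tree = NULL, sites = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(tree)) tree <- simulate_tree(config$n_taxa, config$seed)
  if (is.null(sites))
    sites <- simulate_sites(config$n_sites, config$extent_km, config$n_env,
                            config$spatial_autocorr, config$seed + 1)
  S <- config$n_taxa
  n <- config$n_sites
  set.seed(config$seed + 2)
  gamma <- exp(stats::rnorm(S, 0, 1.5))
  gamma <- gamma / sum(gamma)
  names(gamma) <- tree$tip.label

  env_names <- intersect(EDAPHIC_PANEL$name, colnames(sites))
  E <- scale(as.matrix(sites[, env_names, drop = FALSE]))
  optima <- assign_conserved_traits(tree, config$trait_conservatism,
                                    n_vars = length(env_names),
                                    seed = config$seed + 3)
  colnames(optima) <- env_names

  set.seed(config$seed + 4)
  niche_weights <- function() {
    # sites x taxa Gaussian filter over all environmental variables
    W <- matrix(0, n, S)
    for (v in seq_along(env_names))
      W <- W + outer(E[, v], optima[, v], "-")^2
    exp(-W / (2 * config$niche_strength^2))
  }
  drift_pool <- function() {
    cnt <- matrix(0L, n, S)
    for (i in seq_len(n))
      cnt[i, ] <- cpp_neutral_drift(gamma, config$reads_per_sample,
                                    config$m, 10L)
    cnt
  }
  kernel_mix <- function(comp) {
    d <- as.matrix(geo_distance(sites))
    K <- exp(-config$dispersal_decay * d / max(d))
    K <- sweep(K, 1, rowSums(K), "/")
    K %*% comp
  }
  counts <- switch(config$regime,
    neutral = drift_pool(),
    selection = {
      W <- niche_weights()
      G <- sweep(W, 2, gamma, "*")
      G <- sweep(G, 1, rowSums(G), "/")
      t(sapply(seq_len(n), function(i)
        stats::rmultinom(1, config$reads_per_sample, G[i, ])[, 1]))
    },
    dispersal_limited = {
      comp <- drift_pool() / config$reads_per_sample
      G <- kernel_mix(comp)
      t(sapply(seq_len(n), function(i)
        stats::rmultinom(1, config$reads_per_sample, G[i, ])[, 1]))
    },
    mixed = {
      comp <- drift_pool() / config$reads_per_sample
      G <- kernel_mix(comp) * niche_weights()
      G <- sweep(G, 1, rowSums(G), "/")
      t(sapply(seq_len(n), function(i)
        stats::rmultinom(1, config$reads_per_sample, G[i, ])[, 1]))
    })
  dimnames(counts) <- list(sites$sample_id, tree$tip.label)
  present <- colSums(counts) > 0
  tab <- otu_table(counts[, present, drop = FALSE])
  truth <- list(gamma = gamma, optima = optima, regime = config$regime,
                parameters = unclass(config),
                coordinates = sites[, c("sample_id", "latitude", "longitude")])
  list(table = tab, tree = tree, sites = sites, truth = truth)
}

#' Simulate taxa with step responses along an environmental gradient
#'
#' Each taxon is an increaser (`"z+"`) or decreaser (`"z-"`) with a hard step
#' at its change point (optionally softened to a logistic edge of the given
#' `width`), with negative-binomial read noise.
#'
#' @param n_taxa number of taxa
#' @param gradient numeric gradient value per sample
#' @param change_points change point per taxon (recycled); must lie within the
#'   gradient range
#' @param directions `"z+"` (increaser) or `"z-"` (decreaser), recycled
#' @param noise dispersion of the negative-binomial noise; counts are drawn
#'   with `size = 1 / noise` (so `noise = 1` gives the size-1 overdispersion
#'   typical of amplicon counts); `noise = 0` returns the exact means
#' @param seed integer seed
#' @param base mean abundance on the "high" side of the step
#' @param width logistic edge width in gradient units (0 = hard step)
#' @return list: `table` (an [otu_table()]) and `truth` data.frame
#' @export
simulate_gradient_taxa <- function(n_taxa, gradient, change_points,
                                   directions = "z+", noise = 1, seed = 1,
                                   base = 50, width = 0) {
  if (any(change_points < min(gradient) | change_points > max(gradient)))
    stop("change points outside gradient range")
  set.seed(seed)
  cp <- rep_len(change_points, n_taxa)
  dir <- rep_len(directions, n_taxa)
  n <- length(gradient)
  counts <- matrix(0, n, n_taxa)
  for (k in seq_len(n_taxa)) {
    up <- if (width > 0) stats::plogis((gradient - cp[k]) / width)
          else as.numeric(gradient > cp[k])
    mu <- base * if (dir[k] == "z+") up else 1 - up
    counts[, k] <- if (noise > 0)
      stats::rnbinom(n, mu = mu, size = 1 / noise)
    else round(mu)
  }
  dimnames(counts) <- list(sprintf("S%03d", seq_len(n)),
                           sprintf("g%04d", seq_len(n_taxa)))
  list(table = otu_table(counts),
       truth = data.frame(taxon_id = colnames(counts), change_point = cp,
                          direction = dir))
}

#' Simulate block-correlated taxa for network validation
#'
#' Log-normal abundances driven by one latent factor per block: within-block
#' latent correlation `rho`, between-block 0; Poisson read sampling.
#'
#' @param n_blocks number of independent blocks
#' @param taxa_per_block taxa per block
#' @param rho within-block latent correlation in (0, 1)
#' @param n_samples number of samples
#' @param seed integer seed
#' @param scale Poisson mean multiplier (controls depth)
#' @return list: `table` (an [otu_table()]) and `truth` block assignment
#' @export
simulate_correlated_blocks <- function(n_blocks, taxa_per_block, rho,
                                       n_samples, seed = 1, scale = 20) {
  stopifnot(rho > 0, rho < 1)
  set.seed(seed)
  S <- n_blocks * taxa_per_block
  block <- rep(seq_len(n_blocks), each = taxa_per_block)
  Z <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
  lat <- sqrt(rho) * Z[, block] +
    sqrt(1 - rho) * matrix(stats::rnorm(n_samples * S), n_samples, S)
  mu <- scale * exp(0.8 * lat)
  counts <- matrix(stats::rpois(length(mu), mu), n_samples, S)
  dimnames(counts) <- list(sprintf("S%03d", seq_len(n_samples)),
                           sprintf("b%d_t%02d", block,
                                   rep(seq_len(taxa_per_block), n_blocks)))
  list(table = otu_table(counts),
       truth = data.frame(taxon_id = colnames(counts), block = block))
}
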