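#' Shannon diversity (natural log)
#'
#' @param counts non-negative abundance vector, or an [otu_table()] (one value
#'   per sample).
#' @return H = -sum p_i log p_i over positive entries, in nats.
#' @export
shannon <- function(counts) {
  if (is.matrix(counts)) return(vegan::diversity(unclass(counts), "shannon"))
  if (sum(counts) <= 0) stop("empty sample")
  vegan::diversity(counts, "shannon")
}

#' Chao1 richness estimate (bias-corrected)
#'
#' S_obs + F1 (F1 - 1) / (2 (F2 + 1)), with F1 the number of singletons and F2
#' the number of doubletons; the bias-corrected form is defined even when no
#' doubletons are observed.
#'
#' @param counts integer abundance vector or an [otu_table()] (per-sample
#'   estimates).
#' @export
chao1 <- function(counts) {
  if (is.matrix(counts)) return(apply(unclass(counts), 1, chao1))
  if (any(abs(counts - round(counts)) > 1e-9)) stop("counts must be integers")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha diversity table
#'
#' @param x an [otu_table()]
#' @return data.frame with sample_id, shannon, chao1, observed richness.
#' @export
alpha_diversity <- function(x) {
  data.frame(sample_id = rownames(x),
             shannon = as.numeric(shannon(x)),
             chao1 = as.numeric(chao1(x)),
             richness = rowSums(unclass(x) > 0),
             row.names = NULL)
}

#' Pearson correlations of alpha diversity with environmental variables
#'
#' Thin reporting routine: correlates each alpha-diversity index with each
#' environmental variable (Pearson, pairwise complete observations).
#'
#' @param x an [otu_table()]
#' @param metadata sample metadata aligned with the rows of `x`
#' @param vars environmental variable names
#' @return data.frame: index, variable, r, p
#' @export
alpha_env_correlations <- function(x, metadata, vars) {
  a <- alpha_diversity(x)
  out <- expand.grid(index = c("shannon", "chao1"), variable = vars,
                     stringsAsFactors = FALSE)
  stats_ <- t(apply(out, 1, function(row) {
    ct <- stats::cor.test(a[[row[["index"]]]], metadata[[row[["variable"]]]])
    c(unname(ct$estimate), ct$p.value)
  }))
  out$r <- stats_[, 1]
  out$p <- stats_[, 2]
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' @param x an [otu_table()], relative-abundance matrix, or plain matrix
#'   (samples in rows).
#' @return a labeled [stats::dist] object in `[0, 1]`.
#' @export
bray_curtis <- function(x) {
  if (nrow(x) < 2) stop("need at least two samples")
  vegan::vegdist(unclass(x), method = "bray")
}

#' Great-circle distance in km (haversine, Earth radius 6371 km)
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("coordinates out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

#' Pairwise geographic distance matrix (km) from sample metadata
#'
#' @param metadata data.frame with `latitude`, `longitude` and row-identifying
#'   `sample_id` columns.
#' @return labeled [stats::dist] of great-circle distances in km.
#' @export
geo_distance <- function(metadata) {
  n <- nrow(metadata)
  m <- matrix(0, n, n, dimnames = list(metadata$sample_id,
                                       metadata$sample_id))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- haversine_km(metadata$latitude[i], metadata$longitude[i],
                      metadata$latitude[j], metadata$longitude[j])
    m[i, j] <- d
    m[j, i] <- d
  }
  stats::as.dist(m)
}

unfold <- function(d) {
  m <- as.matrix(d)
  m[lower.tri(m)]
}

#' Distance-decay relationship
#'
#' Ordinary least-squares regression of community similarity (1 - Bray-Curtis)
#' on geographic distance over all unique sample pairs. Both the parametric
#' OLS p-value and a Mantel-style permutation p-value (joint row/column
#' permutation of the similarity matrix) are reported.
#'
#' @param similarity sample similarity matrix/dist (e.g. `1 - bray_curtis(x)`)
#' @param geo geographic distance matrix/dist (km)
#' @param n_perm permutations for the permutation p-value
#' @return list with slope (per km), intercept, r_squared, p_param, p_perm,
#'   n_pairs.
#' @export
distance_decay <- function(similarity, geo, n_perm = 999) {
  s <- as.matrix(similarity)
  g <- as.matrix(geo)
  if (nrow(s) < 3) stop("need at least three samples")
  y <- s[lower.tri(s)]
  x <- g[lower.tri(g)]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  p_param <- summary(fit)$coefficients[2, 4]
  n <- nrow(s)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    yp <- s[p, p][lower.tri(s)]
    bp <- stats::cov(yp, x) / stats::var(x)
    if (abs(bp) >= abs(slope)) exceed <- exceed + 1L
  }
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, p_param = p_param,
       p_perm = (1 + exceed) / (1 + n_perm),
       n_pairs = length(y))
}
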