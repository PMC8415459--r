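# Spatial eigenvector (PCNM) construction, distance-based RDA with Ezekiel
# adjustment, forward selection, three-way variation partitioning, and NMDS
# with environmental vector fitting.

center_gower <- function(d2) {
  n <- nrow(d2)
  H <- diag(n) - matrix(1 / n, n, n)
  -0.5 * H %*% d2 %*% H
}

#' Principal coordinates of neighbor matrices (PCNM)
#'
#' Distances beyond the truncation threshold `t` (default: the longest edge of
#' the minimum spanning tree) are replaced by `4 t`; the truncated matrix is
#' double-centered and eigen-decomposed; positive-eigenvalue vectors, scaled
#' by the square root of their eigenvalue, serve as spatial predictors.
#'
#' @param geo geographic distance matrix or [stats::dist] (km)
#' @param truncation optional threshold overriding the MST rule
#' @return list: `vectors` (sites x axes, columns `PCNM1..`), `values`
#'   (eigenvalues), `truncation`
#' @export
pcnm <- function(geo, truncation = NULL) {
  d <- as.matrix(geo)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 sites")
  t0 <- if (is.null(truncation))
    max(vegan::spantree(stats::as.dist(d))$dist) else truncation
  if (t0 <= 0) stop("duplicate coordinates: truncation distance is zero")
  dt <- d
  dt[dt > t0] <- 4 * t0
  e <- eigen(center_gower(dt^2), symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-8
  if (!any(keep)) stop("no positive PCNM eigenvalues")
  V <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  dimnames(V) <- list(rownames(d), paste0("PCNM", seq_len(ncol(V))))
  list(vectors = V, values = e$values[keep], truncation = t0)
}

pcoa_scores <- function(response_dist) {
  d <- as.matrix(response_dist)
  e <- eigen(center_gower(d^2), symmetric = TRUE)
  keep <- e$values > max(abs(e$values)) * 1e-8
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), sum(keep))
}

r2_on_scores <- function(Y, X) {
  if (is.null(X) || ncol(X) == 0) return(0)
  qrX <- qr(cbind(1, X))
  sum(qr.fitted(qrX, Y)^2) / sum(Y^2)
}

#' Distance-based RDA adjusted R-squared
#'
#' Principal-coordinate transform of the response distances (negative-
#' eigenvalue axes discarded), regression of the site scores on the
#' predictors; `R^2` = constrained / total inertia with the Ezekiel
#' adjustment `1 - (1 - R^2)(n - 1)/(n - p - 1)`.
#'
#' @param response_dist sample dissimilarity matrix (e.g. Bray-Curtis)
#' @param predictors data.frame or matrix of numeric predictors (NULL or
#'   zero columns gives R^2 = 0)
#' @return list: r_squared, adj_r_squared, n, p (predictor rank)
#' @export
dbrda_adjusted_r2 <- function(response_dist, predictors = NULL) {
  Y <- pcoa_scores(response_dist)
  n <- nrow(Y)
  if (is.null(predictors) || NCOL(predictors) == 0)
    return(list(r_squared = 0, adj_r_squared = 0, n = n, p = 0))
  X <- as.matrix(as.data.frame(predictors))
  if (!is.numeric(X)) stop("predictors must be numeric")
  p <- qr(scale(X, scale = FALSE))$rank
  if (p < ncol(X)) stop("rank-deficient predictors")
  if (n <= p + 1) stop("too few samples for the number of predictors")
  r2 <- r2_on_scores(Y, X)
  list(r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1),
       n = n, p = p)
}

#' Forward selection of predictors for dbRDA
#'
#' Greedy selection with the double stopping criterion: the added variable
#' must be significant at `alpha` (permutation test on its marginal R^2 gain)
#' and the cumulative adjusted R^2 may not exceed that of the full candidate
#' model.
#'
#' @param response_dist sample dissimilarity matrix
#' @param candidates data.frame of candidate predictors
#' @param alpha significance threshold for entry
#' @param r2_full adjusted R^2 ceiling (default: the full candidate model)
#' @param n_perm permutations per entry test
#' @return list: `selected` (ordered names), `table` (variable, adj R^2 after
#'   entry, gain, p), `r2_full`
#' @export
forward_select <- function(response_dist, candidates, alpha = 0.05,
                           r2_full = NULL, n_perm = 199) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) == 0) stop("no candidates")
  Y <- pcoa_scores(response_dist)
  n <- nrow(Y)
  adj <- function(r2, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)
  if (is.null(r2_full))
    r2_full <- dbrda_adjusted_r2(response_dist, candidates)$adj_r_squared
  selected <- character(0)
  tab <- data.frame()
  repeat {
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    Xs <- if (length(selected))
      as.matrix(candidates[selected]) else NULL
    r2_base <- r2_on_scores(Y, Xs)
    gains <- vapply(remaining, function(v)
      r2_on_scores(Y, cbind(Xs, candidates[[v]])) - r2_base, numeric(1))
    best <- remaining[which.max(gains)]
    gain_obs <- max(gains)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      zp <- sample(candidates[[best]])
      if (r2_on_scores(Y, cbind(Xs, zp)) - r2_base >= gain_obs)
        exceed <- exceed + 1L
    }
    p_val <- (1 + exceed) / (1 + n_perm)
    adj_new <- adj(r2_base + gain_obs, length(selected) + 1)
    if (p_val >= alpha || adj_new > r2_full) break
    selected <- c(selected, best)
    tab <- rbind(tab, data.frame(variable = best, adj_r_squared = adj_new,
                                 gain = gain_obs, p = p_val))
  }
  list(selected = selected, table = tab, r2_full = r2_full)
}

subset_r2 <- function(response_dist, sets, which_sets) {
  X <- do.call(cbind, lapply(sets[which_sets], as.matrix))
  if (is.null(X) || ncol(X) == 0) return(0)
  # combined sets may alias each other; keep a column basis
  qx <- qr(scale(X, scale = FALSE))
  X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  dbrda_adjusted_r2(response_dist, X)$adj_r_squared
}

#' Three-way variation partitioning (soil / climate / space)
#'
#' Adjusted dbRDA R^2 of all seven non-empty combinations of the three
#' predictor sets; the seven unique fractions (three pure, three pairwise
#' overlaps, one triple overlap) follow by inclusion-exclusion and
#' reconstruct the full-model adjusted R^2 exactly. Pure fractions can be
#' negative (interpret as 0). An empty set contributes 0 with a warning.
#'
#' @param response_dist sample dissimilarity matrix
#' @param soil,climate,space data.frames of (forward-selected) predictors;
#'   `space` is typically the PCNM axes
#' @return list of class `varpart_result`: `fractions` (named list),
#'   `totals` (adj R^2 of each single set and of the full model), `residual`
#' @export
variation_partition <- function(response_dist, soil, climate, space) {
  sets <- list(soil = as.data.frame(soil), climate = as.data.frame(climate),
               space = as.data.frame(space))
  empty <- vapply(sets, function(s) ncol(s) == 0, logical(1))
  if (any(empty))
    warning("empty predictor set(s): ",
            paste(names(sets)[empty], collapse = ", "),
            " (contribute 0)")
  aR <- function(...) subset_r2(response_dist, sets, c(...))
  A <- aR("soil"); B <- aR("climate"); C <- aR("space")
  AB <- aR("soil", "climate"); AC <- aR("soil", "space")
  BC <- aR("climate", "space"); ABC <- aR("soil", "climate", "space")
  g <- A + B + C - AB - AC - BC + ABC
  fr <- list(pure_soil = ABC - BC,
             pure_climate = ABC - AC,
             pure_space = ABC - AB,
             overlap_soil_climate = A + B - AB - g,
             overlap_climate_space = B + C - BC - g,
             overlap_soil_space = A + C - AC - g,
             overlap_all = g)
  structure(list(fractions = fr,
                 totals = list(soil = A, climate = B, space = C,
                               full = ABC),
                 residual = 1 - ABC),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("Variation partitioning (adjusted R^2 fractions):\n")
  for (nm in names(x$fractions))
    cat(sprintf("  %-22s %8.4f\n", nm, x$fractions[[nm]]))
  cat(sprintf("  %-22s %8.4f\n", "residual", x$residual))
  invisible(x)
}

drop_collinear <- function(metadata, vars, rho_max = 0.7) {
  keep <- character(0)
  for (v in vars) {
    ok <- TRUE
    for (w in keep) {
      r <- suppressWarnings(stats::cor(metadata[[v]], metadata[[w]],
                                       method = "spearman"))
      if (!is.na(r) && abs(r) > rho_max) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, v)
  }
  keep
}

#' NMDS ordination with fitted environmental vectors
#'
#' Non-metric multidimensional scaling ([vegan::metaMDS()], multiple random
#' restarts) followed by [vegan::envfit()]. Variables with pairwise
#' |Spearman rho| > 0.7 are discarded beforehand; variables with
#' `R^2 > 0.2` and `p < 0.01` are flagged as key.
#'
#' @param response_dist sample dissimilarity matrix
#' @param metadata sample metadata
#' @param vars variable names to fit
#' @param k ordination dimensions
#' @param n_perm envfit permutations
#' @param trymax NMDS random restarts
#' @return list: `scores` (sites x k), `stress`, `fit` data.frame (variable,
#'   r_squared, p, key), `dropped` (collinear variables)
#' @export
nmds_envfit <- function(response_dist, metadata, vars, k = 2, n_perm = 999,
                        trymax = 20) {
  d <- stats::as.dist(as.matrix(response_dist))
  n <- attr(d, "Size")
  if (n < k + 2) stop("too few samples for k dimensions")
  keep <- drop_collinear(metadata, vars)
  ord <- vegan::metaMDS(d, k = k, trymax = trymax, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  ef <- vegan::envfit(ord, metadata[, keep, drop = FALSE],
                      permutations = n_perm)
  fit <- data.frame(variable = rownames(ef$vectors$arrows),
                    r_squared = ef$vectors$r,
                    p = ef$vectors$pvals, row.names = NULL)
  fit$key <- fit$r_squared > 0.2 & fit$p < 0.01
  list(scores = vegan::scores(ord), stress = ord$stress, fit = fit,
       dropped = setdiff(vars, keep))
}
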