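# Distance-matrix statistics: Mantel tests, correlograms, and multiple
# regression on distance matrices (MRM). All work on the unfolded lower
# triangles of symmetric matrices and use joint row/column permutations for
# inference, with p = (1 + exceedances) / (1 + n_perm).

as_square <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  m
}

#' Mantel test between two distance matrices
#'
#' @param dA,dB symmetric matrices or [stats::dist] objects on the same
#'   samples. Rows/columns of `dB` are permuted jointly.
#' @param n_perm number of permutations
#' @param method `"pearson"` or `"spearman"`
#' @param alternative `"greater"` (default, the usual one-sided Mantel test)
#'   or `"two.sided"`.
#' @return list with r, p, n_permutations.
#' @export
mantel <- function(dA, dB, n_perm = 999, method = c("pearson", "spearman"),
                   alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  a <- as_square(dA)
  b <- as_square(dB)
  stopifnot(nrow(a) == nrow(b))
  x <- a[lower.tri(a)]
  if (stats::sd(x) == 0) stop("constant matrix: Mantel r undefined")
  y <- b[lower.tri(b)]
  if (stats::sd(y) == 0) stop("constant matrix: Mantel r undefined")
  r_obs <- stats::cor(x, y, method = method)
  n <- nrow(a)
  stat <- function(r) if (alternative == "greater") r else abs(r)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    yp <- b[p, p][lower.tri(b)]
    if (stat(stats::cor(x, yp, method = method)) >= stat(r_obs))
      exceed <- exceed + 1L
  }
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm), n_permutations = n_perm)
}

resid_lower <- function(d, controls) {
  y <- d[lower.tri(d)]
  X <- do.call(cbind, lapply(controls, function(m) m[lower.tri(m)]))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) stop("collinear control matrices")
  qr.resid(qrX, y)
}

#' Partial Mantel test
#'
#' Correlation between `dA` and `dB` after removing, from each, the linear
#' effect of one or more control matrices; inference by jointly permuting the
#' rows/columns of `dA` and recomputing the partial correlation.
#'
#' @param dA,dB distance matrices; `...` one or more control matrices.
#' @param n_perm permutations
#' @inheritParams mantel
#' @export
partial_mantel <- function(dA, dB, ..., n_perm = 999,
                           method = c("pearson", "spearman"),
                           alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  controls <- lapply(list(...), as_square)
  if (length(controls) < 1) stop("at least one control matrix required")
  a <- as_square(dA)
  b <- as_square(dB)
  partial_r <- function(am) {
    ra <- resid_lower(am, controls)
    rb <- resid_lower(b, controls)
    stats::cor(ra, rb, method = method)
  }
  r_obs <- partial_r(a)
  n <- nrow(a)
  stat <- function(r) if (alternative == "greater") r else abs(r)
  exceed <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    if (stat(partial_r(a[p, p])) >= stat(r_obs)) exceed <- exceed + 1L
  }
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm), n_permutations = n_perm)
}

#' Mantel correlogram
#'
#' Mantel correlations of `dA` against membership-indicator matrices of
#' distance classes of `dB` (Sturges binning by default), with progressive
#' Holm correction across classes. Delegates to [vegan::mantel.correlog()].
#'
#' @param dA response distance matrix (e.g. pairwise beta-NTI differences)
#' @param dB distance matrix defining classes (e.g. environmental distance)
#' @param n_classes number of classes; `NULL` for Sturges' rule
#' @param n_perm permutations per class
#' @return data.frame: class_index, class_center, n_pairs, r, p, p_holm.
#' @export
mantel_correlogram <- function(dA, dB, n_classes = NULL, n_perm = 999) {
  mc <- vegan::mantel.correlog(as_square(dA), D.geo = as_square(dB),
                               n.class = if (is.null(n_classes)) 0
                                         else n_classes,
                               nperm = n_perm, mult = "holm",
                               progressive = TRUE)
  m <- as.data.frame(mc$mantel.res)
  out <- data.frame(class_index = seq_len(nrow(m)),
                    class_center = m[["class.index"]],
                    n_pairs = m[["n.dist"]],
                    r = m[["Mantel.cor"]],
                    p = m[["Pr(Mantel)"]],
                    p_holm = m[["Pr(corrected)"]])
  out[!is.na(out$r), , drop = FALSE]
}

#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the unfolded response distance matrix on unfolded predictor
#' matrices; permutation p-values for each coefficient and for R^2 obtained by
#' jointly permuting the rows/columns of the response matrix.
#'
#' @param response_dist response distance matrix
#' @param ... named predictor distance matrices
#' @param n_perm permutations
#' @return list with coefficients, p (per coefficient), r_squared, p_r2.
#' @export
mrm <- function(response_dist, ..., n_perm = 999) {
  preds <- lapply(list(...), as_square)
  if (length(preds) == 0) stop("no predictors")
  if (is.null(names(preds)) || any(names(preds) == ""))
    names(preds) <- paste0("X", seq_along(preds))
  ym <- as_square(response_dist)
  X <- cbind(1, do.call(cbind, lapply(preds, function(m) m[lower.tri(m)])))
  colnames(X) <- c("(Intercept)", names(preds))
  if (qr(X)$rank < ncol(X)) stop("collinear predictor matrices")
  y <- ym[lower.tri(ym)]
  if (stats::sd(y) == 0) stop("constant response matrix")
  xtx_inv_xt <- solve(crossprod(X), t(X))
  fit_once <- function(yv) {
    b <- drop(xtx_inv_xt %*% yv)
    res <- yv - X %*% b
    r2 <- 1 - sum(res^2) / sum((yv - mean(yv))^2)
    list(b = b, r2 = r2)
  }
  obs <- fit_once(y)
  n <- nrow(ym)
  exc_b <- numeric(ncol(X))
  exc_r2 <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    f <- fit_once(ym[p, p][lower.tri(ym)])
    exc_b <- exc_b + (abs(f$b) >= abs(obs$b))
    if (f$r2 >= obs$r2) exc_r2 <- exc_r2 + 1L
  }
  list(coefficients = obs$b,
       p = stats::setNames((1 + exc_b) / (1 + n_perm), colnames(X)),
       r_squared = obs$r2,
       p_r2 = (1 + exc_r2) / (1 + n_perm))
}

#' Two-stage MRM
#'
#' Fits an MRM on all predictors, then refits keeping only the predictors
#' significant at `alpha` in the first stage.
#'
#' @inheritParams mrm
#' @param alpha significance level for stage-1 retention
#' @return list with `stage1`, `stage2` (NULL when nothing is retained) and
#'   `retained` predictor names.
#' @export
mrm_two_stage <- function(response_dist, ..., n_perm = 999, alpha = 0.05) {
  preds <- list(...)
  if (is.null(names(preds)) || any(names(preds) == ""))
    names(preds) <- paste0("X", seq_along(preds))
  s1 <- do.call(mrm, c(list(response_dist), preds, list(n_perm = n_perm)))
  keep <- names(preds)[s1$p[names(preds)] < alpha]
  s2 <- if (length(keep))
    do.call(mrm, c(list(response_dist), preds[keep], list(n_perm = n_perm)))
  else NULL
  list(stage1 = s1, stage2 = s2, retained = keep)
}
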