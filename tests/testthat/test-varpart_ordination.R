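test_that("PCNM axes are orthogonal and agree with the vegan construction", {
  md <- simulate_sites(15, seed = 3)
  g <- geo_distance(md)
  p <- pcnm(g)
  cp <- crossprod(p$vectors)
  expect_lt(max(abs(cp - diag(diag(cp)))), 1e-8)
  expect_true(all(p$values > 0))
  ref <- vegan::pcnm(stats::as.dist(as.matrix(g)))
  expect_equal(ncol(p$vectors), ncol(ref$vectors))
  expect_gt(abs(cor(p$vectors[, 1], ref$vectors[, 1])), 0.999)
  # rescaling distances rescales the truncation, not the axis patterns
  p2 <- pcnm(as.matrix(g) * 10)
  expect_equal(p2$truncation, p$truncation * 10, tolerance = 1e-9)
  expect_gt(abs(cor(p2$vectors[, 1], p$vectors[, 1])), 0.999)
  dup <- matrix(0, 4, 4)
  expect_error(pcnm(dup), "truncation distance is zero")
})

test_that("PCNM of equidistant points on a line matches direct eigenanalysis", {
  n <- 12
  d <- as.matrix(dist(seq_len(n)))
  p <- pcnm(d)
  # independent oracle: same truncation rule, direct double-centering
  t0 <- 1 # longest MST edge for equidistant points
  dt <- d
  dt[dt > t0] <- 4 * t0
  H <- diag(n) - 1 / n
  e <- eigen(-0.5 * H %*% dt^2 %*% H, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-8
  expect_equal(p$truncation, t0)
  expect_equal(ncol(p$vectors), sum(keep))
  expect_equal(abs(diag(cor(p$vectors, e$vectors[, keep]))),
               rep(1, sum(keep)), tolerance = 1e-6)
})

test_that("dbRDA adjusted R^2 matches vegan and collapses for pure noise", {
  set.seed(2)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  Y <- matrix(rnorm(60), 20)
  Y[, 1] <- Y[, 1] + 2 * X$a
  d <- dist(Y)
  mine <- dbrda_adjusted_r2(d, X)
  ref <- vegan::RsquareAdj(vegan::dbrda(d ~ a + b, data = X))
  expect_equal(mine$adj_r_squared, ref$adj.r.squared, tolerance = 1e-9)
  expect_equal(mine$r_squared, ref$r.squared, tolerance = 1e-9)
  expect_equal(dbrda_adjusted_r2(d, NULL)$r_squared, 0)
  # permuted predictors explain ~nothing (adjusted may be < 0)
  Xp <- data.frame(a = sample(X$a), b = sample(X$b))
  expect_lt(dbrda_adjusted_r2(d, Xp)$adj_r_squared, 0.1)
  expect_error(dbrda_adjusted_r2(d, cbind(X, a2 = X$a * 2)), "rank")
})

test_that("response built from the predictors drives adjusted R^2 to one", {
  set.seed(3)
  X <- data.frame(a = rnorm(25), b = rnorm(25))
  Y <- cbind(X$a, X$b) # exactly the predictors
  r2 <- dbrda_adjusted_r2(dist(Y), X)$adj_r_squared
  expect_gt(r2, 0.999)
})

test_that("forward selection obeys its double stopping rule", {
  set.seed(4)
  n <- 30
  true_var <- rnorm(n)
  cands <- data.frame(signal = true_var,
                      n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  d <- dist(cbind(2 * true_var, 0.3 * rnorm(n)))
  # with the ceiling released, the alpha rule admits the true driver first
  set.seed(5)
  fs1 <- forward_select(d, cands, r2_full = 1, n_perm = 199)
  expect_equal(fs1$selected[1], "signal")
  # under the default adjusted-R2 ceiling nothing beyond the driver enters
  set.seed(5)
  fs <- forward_select(d, cands, n_perm = 199)
  expect_true(all(fs$selected %in% "signal"))
  expect_true(all(fs$table$adj_r_squared <= fs$r2_full + 1e-9))
  # all-noise candidates: empty set
  set.seed(6)
  noise_only <- data.frame(n1 = rnorm(n), n2 = rnorm(n))
  fs0 <- forward_select(dist(matrix(rnorm(n * 3), n)), noise_only,
                        n_perm = 199)
  expect_length(fs0$selected, 0)
  # deterministic under a fixed seed
  set.seed(7); a <- forward_select(d, cands, n_perm = 99)$selected
  set.seed(7); b <- forward_select(d, cands, n_perm = 99)$selected
  expect_identical(a, b)
})

test_that("variation partitioning reconstructs by inclusion-exclusion", {
  set.seed(8)
  n <- 25
  soil <- data.frame(s1 = rnorm(n))
  climate <- data.frame(c1 = rnorm(n))
  space <- data.frame(p1 = rnorm(n))
  Y <- matrix(rnorm(n * 4), n)
  Y[, 1] <- Y[, 1] + 1.5 * soil$s1
  Y[, 2] <- Y[, 2] + 1.5 * space$p1
  d <- dist(Y)
  vp <- variation_partition(d, soil, climate, space)
  expect_equal(sum(unlist(vp$fractions)), vp$totals$full, tolerance = 1e-9)
  expect_equal(vp$residual, 1 - vp$totals$full, tolerance = 1e-12)
  # matches the vegan reference partition
  ref <- vegan::varpart(d, soil, climate, space)$part$indfract$Adj.R.square
  expect_equal(unname(unlist(vp$fractions)), ref[1:7], tolerance = 1e-9)
  # duplicated partitions push signal into the overlap
  vp2 <- variation_partition(d, soil, soil, space)
  expect_lt(abs(vp2$fractions$pure_soil), 0.05)
  expect_lt(abs(vp2$fractions$pure_climate), 0.05)
  expect_gt(vp2$fractions$overlap_soil_climate, 0.1)
  expect_warning(variation_partition(d, soil, climate,
                                     data.frame(row.names = seq_len(n))),
                 "empty")
})

test_that("space-blind responses yield near-zero pure spatial fractions", {
  set.seed(9)
  n <- 30
  soil <- data.frame(s1 = rnorm(n), s2 = rnorm(n))
  climate <- data.frame(c1 = rnorm(n))
  space <- data.frame(p1 = rnorm(n), p2 = rnorm(n))
  d <- dist(cbind(2 * soil$s1, soil$s2, 0.5 * rnorm(n)))
  vp <- variation_partition(d, soil, climate, space)
  expect_lt(vp$fractions$pure_space, 0.05)
  expect_gt(vp$fractions$pure_soil, 0.3)
})

test_that("NMDS + envfit recover a one-dimensional gradient", {
  set.seed(10)
  n <- 20
  grad <- sort(runif(n, 0, 10))
  md <- data.frame(sample_id = paste0("s", 1:n), grad = grad,
                   noisevar = rnorm(n))
  d <- dist(cbind(grad, 0.05 * rnorm(n)))
  fit <- suppressWarnings(nmds_envfit(d, md, c("grad", "noisevar"),
                                      n_perm = 199))
  expect_lt(fit$stress, 0.05)
  g_row <- fit$fit[fit$fit$variable == "grad", ]
  expect_gt(g_row$r_squared, 0.9)
  expect_true(g_row$key)
  n_row <- fit$fit[fit$fit$variable == "noisevar", ]
  expect_false(isTRUE(n_row$key))
  # collinear variables are pre-filtered
  md$grad_copy <- md$grad + rnorm(n, 0, 1e-3)
  fit2 <- suppressWarnings(nmds_envfit(d, md,
                                       c("grad", "grad_copy", "noisevar"),
                                       n_perm = 49))
  expect_equal(fit2$dropped, "grad_copy")
})
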