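test_that("Shannon diversity matches hand-computed values", {
  expect_equal(shannon(c(10, 10, 10, 10)), log(4))
  expect_equal(shannon(c(5, 0, 5)), log(2))
  expect_equal(shannon(c(1, 2, 3)), 1.0114, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "empty")
  # maximal at uniform composition for fixed richness
  set.seed(1)
  for (k in c(3, 6)) {
    x <- rmultinom(1, 200, runif(k))[, 1]
    expect_lte(shannon(x), log(k) + 1e-12)
  }
})

test_that("Chao1 uses the bias-corrected form", {
  expect_equal(chao1(c(5, 5, 5)), 3) # no singletons
  x <- c(rep(1, 4), rep(2, 2), rep(3, 4)) # S=10, F1=4, F2=2
  expect_equal(chao1(x), 12)
  y <- c(rep(1, 2), rep(3, 8)) # F1=2, F2=0: bias-corrected branch
  expect_equal(chao1(y), 11)
  expect_error(chao1(c(1.5, 2)), "integer")
  tab <- toy_table(seed = 2)
  expect_true(all(chao1(tab) >= rowSums(unclass(tab) > 0)))
})

test_that("alpha-environment correlations report Pearson r and p", {
  # richness gradient: sample i occupies 4 + i taxa evenly
  m <- matrix(0, 20, 30, dimnames = list(paste0("s", 1:20),
                                         paste0("t", 1:30)))
  for (i in 1:20) m[i, seq_len(4 + i)] <- 10
  tab <- otu_table(m)
  set.seed(21)
  md <- data.frame(sample_id = rownames(tab),
                   pH = as.numeric(shannon(tab)) + rnorm(20, 0, 0.05),
                   TN = rnorm(20))
  ac <- alpha_env_correlations(tab, md, c("pH", "TN"))
  expect_equal(nrow(ac), 4)
  sh_ph <- ac[ac$index == "shannon" & ac$variable == "pH", ]
  expect_gt(sh_ph$r, 0.9)
  expect_lt(sh_ph$p, 0.001)
  expect_equal(sh_ph$r,
               unname(cor(shannon(tab), md$pH)), tolerance = 1e-12)
})

test_that("Bray-Curtis dissimilarity matches the hand example and bounds", {
  m <- rbind(a = c(6, 2), b = c(2, 2), c = c(6, 2), d = c(0, 7))
  colnames(m) <- c("t1", "t2")
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 4 / 12)
  expect_equal(d["a", "c"], 0)
  expect_equal(as.matrix(bray_curtis(rbind(x = c(1, 0), y = c(0, 5))))[1, 2],
               1)
  expect_true(all(d >= 0 & d <= 1))
  # invariant to joint rescaling of a pair
  expect_equal(as.matrix(bray_curtis(m * 10))["a", "b"], 4 / 12)
})

test_that("haversine distance is exact on the equator and symmetric", {
  expect_equal(haversine_km(10, 20, 10, 20), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-4)
  expect_equal(haversine_km(12, 100, -5, 103),
               haversine_km(-5, 103, 12, 100))
  expect_error(haversine_km(95, 0, 0, 0), "range")
})

test_that("distance decay recovers an exactly linear similarity field", {
  md <- data.frame(sample_id = paste0("s", 1:8),
                   latitude = seq(22, 25, length.out = 8), longitude = 103)
  g <- as.matrix(geo_distance(md))
  s <- 0.9 - 0.003 * g
  diag(s) <- 1
  dd <- distance_decay(s, g, n_perm = 99)
  expect_equal(dd$slope, -0.003, tolerance = 1e-12)
  expect_equal(dd$r_squared, 1, tolerance = 1e-12)
  expect_equal(dd$n_pairs, 28)
  flat <- distance_decay(matrix(0.5, 8, 8), g, n_perm = 9)
  expect_equal(flat$slope, 0)
})

test_that("Mantel statistics behave at the identities and under permutation", {
  d <- random_distmat(10, seed = 3)
  expect_equal(mantel(d, d, n_perm = 99)$r, 1)
  expect_error(mantel(matrix(1, 5, 5) - diag(5) * 0, d[1:5, 1:5] * 0,
                      n_perm = 9), "constant")
  # r agrees with vegan
  d2 <- random_distmat(10, seed = 4)
  expect_equal(mantel(d, d2, n_perm = 9)$r,
               unname(vegan::mantel(as.dist(d), as.dist(d2),
                                    permutations = 9)$statistic),
               tolerance = 1e-12)
})

test_that("partial Mantel removes and preserves the right structure", {
  set.seed(5)
  dA <- random_distmat(15, seed = 6)
  dB <- 0.7 * dA + random_distmat(15, seed = 7) * 0.3
  dC <- random_distmat(15, seed = 8) # unrelated control
  simple <- mantel(dA, dB, n_perm = 99)$r
  partial <- partial_mantel(dA, dB, dC, n_perm = 99)$r
  expect_equal(partial, simple, tolerance = 0.1)
  # dB constructed from the control: partial r collapses
  dB2 <- 2 * dC + random_distmat(15, seed = 9) * 0.01
  expect_lt(abs(partial_mantel(dA, dB2, dC, n_perm = 99)$r), 0.15)
  # identical response/predictor stays positive given any other control
  expect_gt(partial_mantel(dA, dA, dC, n_perm = 99)$r, 0.9)
})

test_that("Mantel correlogram bins pairs and flags monotone structure", {
  set.seed(1)
  xy <- cbind(runif(30), runif(30))
  db <- as.matrix(dist(xy))
  e <- matrix(rnorm(900, 0, 0.01), 30)
  da <- db + (e + t(e)) / 2
  diag(da) <- 0
  cg <- mantel_correlogram(da, db, n_perm = 99)
  # pairs in the nearest class are more similar than expected (positive r
  # under the class-indicator convention), far classes the opposite
  expect_gt(cg$r[1], 0.2)
  expect_lt(cg$r[1], 1)
  expect_lt(cg$p_holm[1], 0.05)
  expect_lt(cg$r[nrow(cg)], cg$r[1])
  expect_true(all(cg$n_pairs > 0))
})

test_that("MRM recovers exact coefficients and the single-predictor identity", {
  d1 <- random_distmat(12, seed = 10)
  d2 <- random_distmat(12, seed = 11)
  resp <- 2 * d1 + 3 * d2
  fit <- mrm(resp, a = d1, b = d2, n_perm = 49)
  expect_equal(unname(fit$coefficients), c(0, 2, 3), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # single-predictor MRM R^2 equals squared Mantel correlation
  noisy <- d1 + random_distmat(12, seed = 12)
  f1 <- mrm(noisy, a = d1, n_perm = 9)
  expect_equal(f1$r_squared, mantel(noisy, d1, n_perm = 9)$r^2,
               tolerance = 1e-12)
  expect_error(mrm(resp, a = d1, b = d1 * 2, n_perm = 9), "collinear")
})

test_that("two-stage MRM drops pure-noise predictors", {
  set.seed(13)
  d1 <- random_distmat(15, seed = 14)
  noise <- random_distmat(15, seed = 15)
  resp <- 3 * d1 + 0.2 * random_distmat(15, seed = 16)
  ts <- mrm_two_stage(resp, signal = d1, junk = noise, n_perm = 199)
  expect_true("signal" %in% ts$retained)
  expect_false("junk" %in% ts$retained)
  expect_true(all(ts$retained %in% c("signal", "junk")))
})
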