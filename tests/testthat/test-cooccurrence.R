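test_that("pairwise scores hit their closed forms", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
             d = c(1, 1, 1, 1))
  rownames(m) <- paste0("s", 1:4)
  sc <- pairwise_scores(m)
  expect_equal(sc$rho["a", "b"], 1)
  expect_equal(sc$rho["a", "c"], -1)
  expect_equal(sc$bc_sim["a", "b"], 1 - 10 / 30) # sum|a-b| / sum(a+b)
  expect_true(is.na(sc$rho["a", "d"])) # constant taxon flagged
  m2 <- cbind(x = c(1, 2, 3), y = c(2, 4, 6))
  expect_error(pairwise_scores(m2), "4 samples")
})

test_that("ReBoot p-values separate real from degenerate associations", {
  bl <- simulate_correlated_blocks(2, 6, rho = 0.95, n_samples = 30,
                                   seed = 1)
  f <- to_relative_abundance(bl$table)
  hit <- reboot_pvalues(f, c("b1_t01", "b1_t02"), n_perm = 200,
                        n_boot = 200, seed = 2)
  expect_lt(hit$p[["spearman"]], 0.01)
  expect_false(hit$degenerate)
  # constant profiles are degenerate with p = 1
  fc <- f
  fc[, 4] <- 0.2
  deg <- reboot_pvalues(fc, c(1, 4), n_perm = 50, n_boot = 50, seed = 3)
  expect_true(deg$degenerate)
  expect_equal(unname(deg$p), c(1, 1))
})

test_that("Brown's combination reduces to Fisher and to a single p", {
  # zero covariance: Fisher's chi-square on 4 df
  expect_equal(browns_combine(0.05, 0.05, 0), 0.01747866, tolerance = 1e-6)
  expect_equal(browns_combine(0.05, 0.05, 0),
               pchisq(-2 * log(0.05 * 0.05), 4, lower.tail = FALSE),
               tolerance = 1e-9)
  # fully dependent duplicate measure: cov(-2 ln p1, -2 ln p2) = 4, so
  # Var(X) = 16 and the combination collapses to the single p exactly
  for (p in c(0.01, 0.05, 0.2, 0.6))
    expect_equal(browns_combine(p, p, 4), p, tolerance = 1e-9)
  expect_equal(browns_combine(1, 1, 0), 1)
  expect_error(browns_combine(0, 0.5), "positive")
  # empirical covariance of independent uniforms is near zero
  set.seed(4)
  expect_lt(abs(estimate_brown_cov(runif(500), runif(500))), 0.6)
})

test_that("BH adjustment matches the hand-stepped example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(5)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-12))
  expect_equal(bh_adjust(rev(p)), rev(q)) # order invariance
})

test_that("RMT scan rejects Poisson spacing for a GOE-like matrix", {
  set.seed(7)
  W <- matrix(rnorm(3600), 60)
  W <- (W + t(W)) / sqrt(2)
  R <- W / max(abs(W))
  diag(R) <- 1
  rt <- suppressWarnings(rmt_threshold(R, scan = seq(0.1, 0.5, 0.05)))
  expect_lt(rt$scan$poisson_p[1], 0.05) # dense GOE regime: Wigner spacing
  expect_true(rt$threshold >= 0.1 && rt$threshold <= 0.5)
  expect_error(rmt_threshold(R[1:10, 1:10]), "30 taxa")
})

test_that("RMT threshold settles at or below the block correlation", {
  bl <- simulate_correlated_blocks(3, 20, rho = 0.9, n_samples = 50,
                                   seed = 8)
  sc <- pairwise_scores(to_relative_abundance(bl$table))
  rt <- suppressWarnings(rmt_threshold(sc$rho,
                                       scan = seq(0.5, 0.95, 0.05)))
  expect_lte(rt$threshold, 0.9)
  expect_gte(rt$threshold, 0.5)
})

test_that("edge filters enforce both the q and rho thresholds", {
  edges <- data.frame(taxon_1 = c("a", "a", "b", "c"),
                      taxon_2 = c("b", "c", "c", "d"),
                      rho = c(0.9, 0.70, -0.85, 0.80),
                      bc_sim = 0.5, p_spearman = 0.001, p_bc = 0.001,
                      brown_p = 0.001,
                      q = c(0.01, 0.01, 0.02, 0.06),
                      sign = c("+", "+", "-", "+"))
  g <- build_network(edges, q_max = 0.05, rho_min = 0.74,
                     domains = c(a = "bacteria", b = "bacteria",
                                 c = "fungi", d = "fungi"))
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 2) # rho 0.70 and q 0.06 excluded
  expect_false(any(el$from == "a" & el$to == "c"))
  bact <- domain_subgraph(g, "bacteria")
  expect_setequal(igraph::V(bact)$name, c("a", "b"))
  expect_equal(igraph::ecount(bact), 1)
})

test_that("fast-greedy modules recover planted blocks and closed-form Q", {
  tri2 <- igraph::make_graph(~ a - b, b - c, c - a, x - y, y - z, z - x)
  mods <- fast_greedy_modules(tri2)
  expect_equal(mods$modularity, 0.5)
  expect_equal(length(mods$sizes), 2)
  clique <- igraph::make_full_graph(5)
  expect_equal(fast_greedy_modules(clique)$modularity, 0)
  expect_equal(length(fast_greedy_modules(clique)$sizes), 1)
})

test_that("module eigengene summarizes member profiles", {
  set.seed(9)
  base <- sort(rnorm(20))
  X <- sapply(1:5, function(i) base + rnorm(20, 0, 0.05))
  colnames(X) <- paste0("t", 1:5)
  rownames(X) <- paste0("s", 1:20)
  eg <- module_eigengene(X, colnames(X))
  expect_gt(eg$variance_explained, 0.95)
  expect_gt(cor(eg$eigengene, base), 0.99)
  # flipping member profiles flips the eigengene
  eg2 <- module_eigengene(-X, colnames(X))
  expect_lt(cor(eg$eigengene, eg2$eigengene), -0.99)
  md <- data.frame(sample_id = rownames(X), grad = base + rnorm(20, 0, 0.1))
  eg3 <- module_eigengene(X, colnames(X), md, "grad")
  expect_gt(abs(eg3$env_cor[["grad"]]), 0.7)
  expect_error(module_eigengene(X, c("t1", "t2")), "at least 3")
})

test_that("local networks report exact topology for known subgraphs", {
  g <- igraph::make_graph(~ a - b, a - c, b - c, # triangle in s1
                          p - q, q - r, r - s)   # path in s2
  m <- rbind(s1 = c(a = 1, b = 2, c = 1, p = 0, q = 0, r = 0, s = 0),
             s2 = c(a = 0, b = 0, c = 0, p = 3, q = 1, r = 2, s = 1))
  tab <- otu_table(m)
  lf <- local_networks(g, tab)
  expect_equal(lf["s1", "density"], 1)
  expect_equal(lf["s1", "diameter"], 1)
  expect_equal(lf["s2", "diameter"], 3)
  expect_equal(lf["s2", "n_edges"], 3)
  fd <- local_feature_distance(rbind(lf, s3 = lf["s1", ] * 1.1))
  dm <- as.matrix(fd$dist)
  expect_equal(dm[1, 1], 0)
  expect_equal(dm[1, 2], dm[2, 1])
  m_bad <- rbind(s1 = c(a = 1, b = 0, c = 0, p = 0, q = 0, r = 0, s = 0))
  expect_error(local_networks(g, otu_table(m_bad)), "fewer than 2")
})

test_that("network-topology spatial regression degrades gracefully", {
  set.seed(10)
  n <- 12
  geo <- random_distmat(n, seed = 11)
  feat <- geo * 0.5 + random_distmat(n, seed = 12) * 0.1
  env <- list(e1 = random_distmat(n, seed = 13))
  tv <- topology_vs_space(feat, geo, env, n_perm = 99)
  expect_gt(tv$slope, 0.3)
  expect_true(all(tv$mrm$retained %in% c("geo", "e1")))
  # identical local networks everywhere: zero slope, MRM skipped
  z <- geo * 0
  expect_warning(tv0 <- topology_vs_space(z, geo, n_perm = 9), "constant")
  expect_equal(tv0$slope, 0)
  expect_null(tv0$mrm)
})

test_that("degree distribution table supports the scale-free inspection", {
  g <- igraph::sample_pa(60, m = 2, directed = FALSE)
  dd <- degree_distribution_table(g)
  expect_true(all(dd$table$degree >= 1))
  expect_lt(dd$loglog_slope, 0)
})
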