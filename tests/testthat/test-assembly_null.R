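test_that("beta-MNTD matches hand evaluation and is symmetric", {
  D <- matrix(c(0, 1, 3,
                1, 0, 2,
                3, 2, 0), 3, byrow = TRUE,
              dimnames = list(paste0("t", 1:3), paste0("t", 1:3)))
  fi <- c(t1 = 1, t2 = 0, t3 = 0)
  fj <- c(t1 = 0, t2 = 0.5, t3 = 0.5)
  expect_equal(beta_mntd(fi, fj, D), 1.5)
  expect_equal(beta_mntd(fj, fi, D), 1.5)
  expect_equal(beta_mntd(fi, fi, D), 0)
  expect_equal(beta_mntd(c(t1 = 1, t2 = 0, t3 = 0),
                         c(t1 = 0, t2 = 1, t3 = 0), D), 1)
  expect_error(beta_mntd(c(tX = 1), fj, D), "missing")
})

test_that("beta-MNTD engine agrees with picante on a simulated community", {
  tr <- simulate_tree(25, seed = 2)
  cfg <- simulation_config(n_sites = 8, n_taxa = 25, reads_per_sample = 150,
                           regime = "neutral", seed = 3)
  sim <- simulate_regime(cfg, tree = tr)
  f <- to_relative_abundance(sim$table)
  ours <- bnti(sim$table, tr, n_null = 2, seed = 1)$bmntd
  ref <- as.matrix(picante::comdistnt(f, cophenetic(tr),
                                      abundance.weighted = TRUE))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-9)
})

test_that("degenerate beta-NTI nulls are flagged", {
  star <- read_newick("(t1:1,t2:1,t3:1,t4:1);")
  m <- rbind(s1 = c(5, 5, 0, 0), s2 = c(0, 0, 5, 5), s3 = c(5, 5, 0, 0))
  colnames(m) <- paste0("t", 1:4)
  res <- bnti(otu_table(m), star, n_null = 30, seed = 1)
  expect_true(all(res$pairs$degenerate)) # label shuffles cannot change a star
  expect_true(all(is.na(res$pairs$bnti)))
  # identical communities: obs = null = 0
  expect_true(res$pairs$degenerate[res$pairs$sample_i == "s1" &
                                     res$pairs$sample_j == "s3"])
  expect_error(bnti(otu_table(m), star, n_null = 1), "n_null")
})

test_that("Raup-Crick hits its analytic anchors", {
  # identical pair inside a diverse metacommunity: nulls almost surely differ
  set.seed(4)
  m <- matrix(rpois(10 * 40, 4), 10, 40,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:40)))
  m[2, ] <- m[1, ]
  rc <- raup_crick_bray(otu_table(m), n_null = 199, seed = 5)
  expect_lt(rc$rc["s1", "s2"], -0.9)
  expect_true(all(rc$pairs$rc_bray >= -1 & rc$pairs$rc_bray <= 1))
  # one-taxon metacommunity: every null equals the observation
  one <- otu_table(matrix(c(5L, 8L, 3L), 3, 1,
                          dimnames = list(paste0("s", 1:3), "t1")))
  rc1 <- raup_crick_bray(one, n_null = 99, seed = 6)
  expect_true(all(rc1$pairs$rc_bray == 0))
})

test_that("pair classification follows the beta-NTI / RC decision rules", {
  expect_equal(classify_pair(2.5), "variable_selection")
  expect_equal(classify_pair(-2.5), "homogeneous_selection")
  expect_equal(classify_pair(1.0, 0.97), "dispersal_limitation")
  expect_equal(classify_pair(1.0, -0.97), "homogenizing_dispersal")
  expect_equal(classify_pair(0, 0), "undominated")
  # degenerate null falls through to the RC rules
  expect_equal(classify_pair(NA, 0.99, degenerate = TRUE),
               "dispersal_limitation")
  expect_error(classify_pair(c(2.5, 1.0)), "RC values required")
  expect_equal(classify_pair(c(3, -3, 0.5), c(NA, NA, 0.2)),
               c("variable_selection", "homogeneous_selection",
                 "undominated"))
})

test_that("process summary fractions, SDER and RC stochasticity", {
  labels <- c(rep("variable_selection", 5), rep("homogeneous_selection", 1),
              rep("dispersal_limitation", 2), rep("undominated", 2))
  ps <- process_summary(labels)
  expect_equal(sum(ps$fractions), 1, tolerance = 1e-12)
  expect_equal(ps$sder_null, 0.6 / 0.2, tolerance = 1e-9)
  und <- process_summary(rep("undominated", 4))
  expect_true(is.nan(und$sder_null))
  expect_false(und$sder_null_defined)
  rc <- c(0.99, -0.2, 0.3, 0.97, -0.99)
  ps2 <- process_summary(labels, rc = rc)
  expect_equal(ps2$stochastic_fraction_rc, 3 / 5)
  expect_equal(ps2$rc_within_null_fraction, 2 / 5)
})

test_that("phylogenetic-signal pretest detects conserved niches", {
  tr <- simulate_tree(60, seed = 1)
  cfg <- simulation_config(n_sites = 25, n_taxa = 60,
                           reads_per_sample = 600, regime = "selection",
                           niche_strength = 0.6, trait_conservatism = 1,
                           seed = 2)
  sim <- simulate_regime(cfg, tree = tr)
  vars <- intersect(c("pH", "OM", "TN", "TP", "TK", "AN"),
                    colnames(sim$sites))
  sig <- phylo_signal(sim$table, tr, sim$sites, vars, n_perm = 199)
  expect_gt(sig$correlogram$r[1], 0) # similar niches among close relatives
  expect_true(sig$signal)
  md_const <- sim$sites
  md_const$pH <- 5
  expect_error(phylo_signal(sim$table, tr, md_const, "pH"), "constant")
})

test_that("environmental drivers of beta-NTI are ranked and ranked first", {
  set.seed(7)
  n <- 20
  md <- data.frame(sample_id = paste0("s", 1:n),
                   latitude = runif(n, 22, 25), longitude = runif(n, 100, 106),
                   pH = rnorm(n), TN = rnorm(n), AP = rnorm(n))
  geo <- as.matrix(geo_distance(md))
  rownames(geo) <- colnames(geo) <- md$sample_id
  bn <- as.matrix(dist(scale(md$pH))) * 0.9 +
    as.matrix(dist(rnorm(n))) * 0.2
  dimnames(bn) <- list(md$sample_id, md$sample_id)
  drv <- bnti_env_drivers(bn, md, geo, c("pH", "TN", "AP"), n_perm = 199)
  expect_equal(drv$best, "pH")
  expect_gt(drv$ranking$r[1], 0.5)
  expect_lt(drv$ranking$p[1], 0.05)
  expect_gt(drv$partial$r, 0.3)
  expect_error(bnti_env_drivers(bn * 0, md, geo, c("pH", "TN")), "constant")
})

test_that("full assembly analysis labels every pair consistently", {
  tr <- simulate_tree(40, seed = 8)
  cfg <- simulation_config(n_sites = 10, n_taxa = 40,
                           reads_per_sample = 300, regime = "selection",
                           niche_strength = 0.6, seed = 9)
  sim <- simulate_regime(cfg, tree = tr)
  ap <- assembly_processes(sim$table, tr, n_null = 199, seed = 10)
  expect_equal(nrow(ap$pairs), choose(10, 2))
  expect_true(all(ap$pairs$process %in%
                    c("variable_selection", "homogeneous_selection",
                      "dispersal_limitation", "homogenizing_dispersal",
                      "undominated")))
  expect_equal(sum(ap$summary$fractions), 1, tolerance = 1e-12)
  # labels consistent with thresholds row by row
  with(ap$pairs, {
    sel <- !degenerate & bnti > 2
    expect_true(all(process[sel] == "variable_selection"))
    disp <- (degenerate | abs(bnti) <= 2) & rc_bray > 0.95
    expect_true(all(process[disp] == "dispersal_limitation"))
  })
})
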