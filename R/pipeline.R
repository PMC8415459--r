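# Pipeline orchestration: runs the analysis stages in dependency order from a
# configuration list (or YAML file), writing per-stage outputs and a manifest.

PIPELINE_STAGES <- c("simulate", "preprocess", "diversity", "assembly",
                     "neutral", "varpart", "titan", "network")

pget <- function(cfg, key, default) {
  v <- cfg[[key]]
  if (is.null(v)) default else v
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on either simulated data
#' (stage `"simulate"`) or files named in the config (`otu_table`, `tree`,
#' `metadata`). Writes per-stage outputs plus a `manifest.json` recording the
#' package version, seed, parameters and stages to `out_dir`.
#'
#' Config keys (all optional unless a stage needs them): `out_dir`, `seed`,
#' `stages` (subset of simulate, preprocess, diversity, assembly, neutral,
#' varpart, titan, network, or `"all"`), `otu_table`/`tree`/`metadata` input
#' paths, `orientation`, `simulate` (arguments to [simulation_config()]),
#' `min_total`, `rarefy_depth`, `min_rel`, `n_null`, `titan_variable`,
#' `titan_n_perm`, `titan_n_boot`, `rho_min`, `edge_n_perm`, `edge_n_boot`.
#'
#' @param config a named list, or path to a YAML file with one
#' @return invisible list of stage results
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- pget(config, "out_dir", "ecoassembly_out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- pget(config, "seed", 1)
  stages <- pget(config, "stages", "all")
  if (identical(stages, "all") || "all" %in% stages) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  say <- function(...) message("[ecoassembly] ", ...)
  results <- list()

  tab <- NULL; tree <- NULL; md <- NULL
  if ("simulate" %in% stages) {
    say("simulate")
    sim_args <- pget(config, "simulate", list())
    sim_args$seed <- pget(sim_args, "seed", seed)
    cfg <- do.call(simulation_config, sim_args)
    sim <- simulate_regime(cfg)
    tab <- sim$table; tree <- sim$tree; md <- sim$sites
    write_otu_table(tab, file.path(out_dir, "otu_table.tsv"))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    utils::write.csv(md, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(regime = sim$truth$regime,
                              parameters = sim$truth$parameters),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    results$simulate <- sim
  } else {
    if (!is.null(config$otu_table))
      tab <- read_otu_table(config$otu_table,
                            orientation = pget(config, "orientation",
                                               "samples"))
    if (!is.null(config$tree)) tree <- read_newick(config$tree)
    if (!is.null(config$metadata))
      md <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
  }
  need_table <- setdiff(stages, "simulate")
  if (length(need_table) && is.null(tab))
    stop("stages ", paste(need_table, collapse = ", "),
         " need an OTU table (input file or simulate stage)")

  if ("preprocess" %in% stages) {
    say("preprocess")
    tab <- filter_min_total_count(tab, pget(config, "min_total", 10))
    depth <- pget(config, "rarefy_depth", NULL)
    if (!is.null(depth)) tab <- rarefy(tab, depth, seed)
    write_otu_table(tab, file.path(out_dir, "otu_table_preprocessed.tsv"))
    results$preprocess <- tab
  }

  env_vars <- intersect(EDAPHIC_PANEL$name, colnames(md))

  if ("diversity" %in% stages) {
    say("diversity")
    alpha <- alpha_diversity(tab)
    write_results(alpha, file.path(out_dir, "alpha_diversity.tsv"), "tsv")
    bc <- bray_curtis(tab)
    write_results(as.matrix(bc), file.path(out_dir, "bray_curtis.tsv"),
                  "tsv")
    res <- list(alpha = alpha, bray_curtis = bc)
    if (!is.null(md)) {
      geo <- geo_distance(md)
      res$ddr <- distance_decay(1 - as.matrix(bc), geo)
      jsonlite::write_json(res$ddr, file.path(out_dir, "ddr.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    results$diversity <- res
  }

  if ("assembly" %in% stages) {
    say("assembly (null models)")
    if (is.null(tree)) stop("assembly stage needs a tree")
    ap <- assembly_processes(tab, tree, n_null = pget(config, "n_null", 999),
                             seed = seed)
    write_results(ap$pairs, file.path(out_dir, "assembly_pairs.tsv"), "tsv")
    jsonlite::write_json(ap$summary,
                         file.path(out_dir, "assembly_summary.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    results$assembly <- ap
  }

  if ("neutral" %in% stages) {
    say("neutral model & niche metrics")
    fit <- fit_sloan(tab)
    write_results(fit$taxa, file.path(out_dir, "sloan_taxa.tsv"), "tsv")
    jsonlite::write_json(fit[c("m", "N", "d", "r_squared", "aic_neutral",
                               "aic_binomial")],
                         file.path(out_dir, "sloan_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    bcom <- community_niche_breadth(tab)
    disp <- dispersal_ability(tab)
    jsonlite::write_json(list(bcom_mean = mean(bcom), D = disp$D),
                         file.path(out_dir, "niche_dispersal.json"),
                         auto_unbox = TRUE, digits = NA)
    results$neutral <- list(sloan = fit, bcom = bcom, dispersal = disp)
  }

  if ("varpart" %in% stages) {
    say("variation partitioning")
    if (is.null(md)) stop("varpart stage needs metadata")
    bc <- bray_curtis(tab)
    geo <- geo_distance(md)
    sp <- as.data.frame(pcnm(geo)$vectors)
    soil <- md[, env_vars, drop = FALSE]
    climate <- md[, intersect(c("elevation", "MAT", "MAP"), colnames(md)),
                  drop = FALSE]
    sel <- function(cands) forward_select(bc, cands)$selected
    vp <- variation_partition(bc,
                              soil[, sel(soil), drop = FALSE],
                              climate[, sel(climate), drop = FALSE],
                              sp[, sel(sp), drop = FALSE])
    jsonlite::write_json(list(fractions = vp$fractions,
                              totals = vp$totals, residual = vp$residual),
                         file.path(out_dir, "varpart.json"),
                         auto_unbox = TRUE, digits = NA)
    nm <- nmds_envfit(bc, md, env_vars)
    write_results(nm$fit, file.path(out_dir, "envfit.tsv"), "tsv")
    results$varpart <- list(varpart = vp, nmds = nm)
  }

  if ("titan" %in% stages) {
    say("TITAN thresholds")
    if (is.null(md)) stop("titan stage needs metadata")
    tv <- pget(config, "titan_variable", env_vars[1])
    tt <- titan(tab, md[[tv]],
                n_perm = pget(config, "titan_n_perm", 250),
                n_boot = pget(config, "titan_n_boot", 500), seed = seed)
    write_results(tt$taxa, file.path(out_dir, "titan_taxa.tsv"), "tsv")
    write_results(tt$community$curve,
                  file.path(out_dir, "titan_curve.tsv"), "tsv")
    results$titan <- tt
  }

  if ("network" %in% stages) {
    say("co-occurrence network")
    nt <- filter_rare_relative(tab, pget(config, "min_rel", 1e-4))
    se <- score_edges(nt, rho_min = pget(config, "rho_min", NULL),
                      n_perm = pget(config, "edge_n_perm", 1000),
                      n_boot = pget(config, "edge_n_boot", 1000),
                      seed = seed)
    write_results(se$edges, file.path(out_dir, "edges.tsv"), "tsv")
    g <- build_network(se$edges, rho_min = se$rho_min,
                       domains = stats::setNames(domain_tags(nt),
                                                 colnames(nt)))
    mods <- fast_greedy_modules(g)
    igraph::V(g)$module <- as.integer(mods$membership[igraph::V(g)$name])
    write_results(g, file.path(out_dir, "network.graphml"), "graphml")
    write_results(g, file.path(out_dir, "network_edges.tsv"), "edge-list")
    jsonlite::write_json(list(modularity = mods$modularity,
                              n_modules = length(mods$sizes),
                              dominant = mods$dominant),
                         file.path(out_dir, "modules.json"),
                         auto_unbox = TRUE, digits = NA)
    results$network <- list(edges = se, graph = g, modules = mods)
  }

  manifest <- list(package = "ecoassembly",
                   version = as.character(utils::packageVersion("ecoassembly")),
                   r_version = as.character(getRversion()),
                   date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = seed, stages = stages,
                   parameters = config[setdiff(names(config),
                                               c("stages", "out_dir"))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  say("done: ", out_dir)
  invisible(results)
}
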