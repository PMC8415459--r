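# ecoassembly

Community assembly processes in microbial metacommunities: who shaped this
community — selection, dispersal, or drift?

`ecoassembly` is an R package for ecologists analysing regional amplicon
surveys (an OTU count table, a rooted phylogeny, sample coordinates and
environmental measurements). It implements the full statistical stack used
to partition ecological assembly processes between bacteria- and
fungi-like communities:

* **Null-model process partitioning** — abundance-weighted βMNTD and the
  β-nearest taxon index (βNTI) against a tip-shuffling phylogenetic null,
  Raup–Crick on Bray–Curtis (RC_Bray) against a richness- and
  read-preserving taxonomic null, five-way classification of community
  pairs (|βNTI| > 2 → variable/homogeneous selection; |RC| > 0.95 →
  dispersal limitation / homogenizing dispersal; else undominated), and
  the selection-to-dispersal-limitation effect ratio (SDER). The heavy
  null loops run in C++.
* **Sloan's neutral community model** — occurrence frequency vs mean
  relative abundance, `f_pred = 1 − BetaCDF(d; Nmp̄, Nm(1−p̄))`, single
  migration parameter *m*, generalized R², and an AIC comparison against
  the binomial random-sampling null.
* **Niche & dispersal metrics** — Levins niche breadth `B = 1/Σ P_i²`,
  community means *Bcom*, pairwise shared-abundance dispersal index *D*.
* **Variation partitioning** — PCNM spatial eigenvectors (MST truncation),
  dbRDA with Ezekiel-adjusted R², double-stopping forward selection, and
  the three-way soil/climate/space partition by inclusion–exclusion.
* **TITAN community thresholds** — per-taxon IndVal change points with
  permutation z-scores and bootstrap purity/reliability; community-level
  sum(z−)/sum(z+) peaks along environmental gradients.
* **Co-occurrence networks** — Spearman + Bray–Curtis edge scores, ReBoot
  permutation/bootstrap p-values with compositional renormalization,
  Brown's p-value combination, BH correction, random-matrix-theory
  correlation thresholds, fast-greedy modules and modularity, module
  eigengenes, and per-sample local-network topology with MRM.
* **Distance-matrix statistics** — Mantel, partial Mantel, Mantel
  correlograms, multiple regression on distance matrices (two-stage), and
  distance-decay regressions.
* **A synthetic metacommunity generator** — neutral drift (Hubbell
  death–replacement with migration *m*), Gaussian environmental selection
  on phylogenetically conserved niches, and kernel-based dispersal
  limitation, with ground truth emitted for every run — so each stage of
  the stack is validated against data whose assembly process is known.

## Worked example

Simulate a 40-site metacommunity assembled by environmental selection on
phylogenetically conserved niches, then ask the null models who did it:

```r
library(ecoassembly)

cfg <- simulation_config(n_sites = 40, n_taxa = 300,
                         reads_per_sample = 2000,
                         regime = "selection", seed = 7)
sim <- simulate_regime(cfg)

tab <- filter_min_total_count(sim$table, 10)
tab
#> OTU table: 40 samples x 270 taxa, 79,856 reads total

ap <- assembly_processes(tab, sim$tree, n_null = 999, seed = 8)
round(ap$summary$fractions, 3)
#>     variable_selection  homogeneous_selection   dispersal_limitation
#>                  0.692                  0.000                  0.224
#> homogenizing_dispersal            undominated
#>                  0.003                  0.081
ap$summary$sder_null
#> [1] 3.09
```

69% of community pairs show βNTI > 2 — the null models correctly report
that selection dominates this landscape, with an SDER of about 3. The
neutral-model fit on the same table:

```r
fit_sloan(tab)
#> Sloan neutral model: m = 0.0753, N = 1996.4, d = 5.01e-04
#> generalized R^2 = 0.216
#> AIC neutral = -886.15, AIC binomial = -530.74 (neutral preferred)
```

The low generalized R² is itself diagnostic: a strongly selected
metacommunity is poorly described by neutral occupancy, even though the
one-parameter neutral curve still beats the parameter-free binomial null.

A complete pipeline (preprocessing → diversity → null models → neutral →
variation partitioning → TITAN → networks) can be driven from a config
list or YAML file via `run_pipeline()`, or from the command line with
`inst/cli/ecoassembly.R`.

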