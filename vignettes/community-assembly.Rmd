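---
title: "Partitioning microbial community assembly processes with ecoassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning microbial community assembly processes with ecoassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoassembly)
```

## The problem

Microbial communities across a landscape are assembled by a mixture of
deterministic processes (environmental selection) and stochastic ones
(dispersal, ecological drift). Quantifying their relative importance from
amplicon surveys — an OTU count table, a phylogeny, sample coordinates and
environmental measurements — is the purpose of this package. It implements
the complete analysis stack used in regional rhizosphere and soil surveys:

* **phylogenetic + taxonomic null models** (βMNTD/βNTI and Raup–Crick on
  Bray–Curtis) that classify each community pair into variable selection,
  homogeneous selection, dispersal limitation, homogenizing dispersal, or
  undominated, and summarize the selection-to-dispersal-limitation effect
  ratio (SDER);
* **Sloan's neutral community model**, fitted against a binomial
  random-sampling comparison, whose single migration parameter *m* indexes
  dispersal limitation;
* **niche and dispersal traits**: Levins niche breadth *B*, its per-sample
  community mean *Bcom*, and the pairwise shared-abundance dispersal index
  *D*;
* **variation partitioning** of Bray–Curtis β-diversity into edaphic,
  climatic and spatial (PCNM) components with forward selection;
* **TITAN-style community thresholds** along environmental gradients;
* **co-occurrence networks** with ReBoot permutation/bootstrap edge
  significance, Brown's p-value combination, BH correction,
  random-matrix-theory thresholding, fast-greedy modules, eigengenes, and
  per-sample local network topology.

Because the statistics are null-model based, every stage is validated
against a synthetic metacommunity generator whose assembly regime is known
by construction.

## The null-model framework

For a pair of communities $i, j$ the abundance-weighted β-mean nearest taxon
distance is

$$\beta\mathrm{MNTD}_{ij} = \tfrac12\Big[\sum_k f_{ik}\,\min_{l \in j} d_{kl}
  + \sum_l f_{jl}\,\min_{k \in i} d_{lk}\Big],$$

with $f_{ik}$ relative abundances and $d_{kl}$ cophenetic distances. The
null shuffles taxon labels across the tips of the whole tree ("taxa
labels" randomization) and

$$\beta\mathrm{NTI} = \frac{\beta\mathrm{MNTD}_{\mathrm{obs}} -
  \overline{\beta\mathrm{MNTD}}_{\mathrm{null}}}{\mathrm{sd}
  (\beta\mathrm{MNTD}_{\mathrm{null}})}.$$

$\beta\mathrm{NTI} > 2$ marks variable selection, $< -2$ homogeneous
selection. Remaining pairs are classified by the Raup–Crick metric on
Bray–Curtis: null communities preserve each sample's richness (taxa drawn
without replacement proportional to occurrence frequency) and read total
(one read per drawn taxon, the rest multinomial proportional to
metacommunity relative abundance), and

$$\mathrm{RC} = 2\,\frac{\#\{\mathrm{null} < \mathrm{obs}\} +
  \tfrac12\#\{\mathrm{null} = \mathrm{obs}\}}{n_{\mathrm{null}}} - 1
  \in [-1, 1].$$

$\mathrm{RC} > 0.95$ indicates dispersal limitation, $< -0.95$ homogenizing
dispersal, the rest undominated. Pairs whose βNTI null is degenerate
(zero spread, e.g. on a star phylogeny) fall through to the RC rules rather
than aborting the run. SDER is the summed selection fraction divided by the
dispersal-limitation fraction; a VPA-based variant divides the pure
environmental by the pure spatial adjusted $R^2$.

A valid βNTI analysis requires phylogenetic signal in the niche: the
`phylo_signal()` pretest relates abundance-weighted niche distances to
cophenetic distances by a Mantel correlogram. Throughout the package the
correlogram uses the class-indicator convention of `vegan::mantel.correlog`
— a *positive* correlation at a distance class means pairs inside that
class are more similar than expected, so phylogenetic signal appears as
significant positive correlation at the *shortest* phylogenetic classes.

## The neutral model and its recovery bias

`fit_sloan()` fits the occurrence–abundance relationship
$f_{\mathrm{pred}}(\bar p) = 1 - \mathrm{Beta}(d;\, N m \bar p,\,
N m (1 - \bar p))$ by least squares over taxa, with $N$ the mean reads per
sample and detection limit $d = 1/N$ (the convention of the standard
implementation). `binomial_null_fit()` provides the zero-parameter
random-sampling comparison; both models are scored with the least-squares
AIC $n \ln(\mathrm{SS}/n) + 2k$ so they are directly comparable.

One property matters for interpretation. The generator's drift sampler is
an exact Moran process (death–replacement with migration probability *m*),
and its stationary distribution matches the Beta approximation well for
abundant taxa — but for rare taxa the discrete process yields
$P(\mathrm{absent}) = m^{N m p/(1-m)}$, more *presences* than the Beta
predicts. Fitted against the Beta curve, exact Moran data therefore return
an *m* inflated by roughly 1.6–1.9× at the simulated scales, even though
the curve fit is excellent ($R^2 > 0.95$) and the fitted *m* is strictly
monotone in the generating *m*. The package's tests assert the monotone
rank recovery; absolute recovery of the Moran migration probability is not
a property of the standard fit and should not be expected of it on real
data either. *m* is best read as a comparative index, which is exactly how
it is used when contrasting community domains.

## The synthetic metacommunity generator

`simulate_regime()` produces an OTU table plus ground truth under four
regimes, sharing a lognormal regional pool $\gamma$ (meanlog 0, sdlog 1.5,
a typical amplicon rank-abundance spread), a pure-birth phylogeny of depth
1, and spatially structured sites (box diagonal 650 km, matching a
regional survey's extent; environmental fields mix a squared-exponential
spatial Gaussian process with iid noise via `spatial_autocorr`):

* **neutral** — independent Hubbell drift per site: multinomial
  initialization from $\gamma$, then $10 \times$ community-size
  death–replacement events with regional replacement probability *m*.
  Default $m = 0.25$, the well-dispersed (bacteria-like) migration rate
  estimated in regional rhizosphere surveys.
* **selection** — the pool is filtered per site by Gaussian niche weights
  $\exp(-(E_v - o_{kv})^2 / 2\sigma^2)$ over all environmental variables,
  with per-taxon optima $o_{kv}$ evolved by Brownian motion on the tree and
  blended with iid noise by the conservatism parameter $\lambda$
  ($\lambda = 1$ fully conserved, enabling βNTI to see selection).
* **dispersal_limited** — drift communities (default $m = 0.014$, the
  dispersal-limited, fungi-like estimate) are blended across sites with an
  exponential kernel $\exp(-\kappa\, d_{ij}/d_{\max})$; $\kappa = 0$
  homogenizes completely, large $\kappa$ preserves local divergence and
  produces distance decay. Default $\kappa = 20$.
* **mixed** — selection weights applied to the kernel-blended pools.

The migration defaults are deliberately regime-specific: a migration rate
of 0.25 contradicts what "dispersal limited" means, so that regime defaults
to the low value, and both anchors come from published neutral-model fits
of the two microbial domains.

What the generator does *not* emulate: sequencing error, chimeras,
compositional biases of extraction/PCR, taxon-specific detection
efficiencies, temporal dynamics, or realistic taxonomies. Passing tests
demonstrate that the statistics recover *known* structure of an idealized
metacommunity; they cannot certify performance on real amplicon data.

A known sensitivity: the detectability of dispersal limitation by
Raup–Crick depends on the evenness of the drawn regional pool. When the
lognormal draw happens to concentrate $>40\%$ of $\gamma$ in the ten most
abundant taxa, drift turnover among the dominants is small relative to the
null's spread and the dispersal-limitation fraction can collapse toward
zero for that landscape; flatter pools yield fractions of 0.2–0.7 at the
default settings. Replicate landscapes (different seeds) average over this.

## Variation partitioning and forward selection

PCNM spatial predictors truncate the great-circle distance matrix at the
longest minimum-spanning-tree edge $t$ (larger distances replaced by $4t$),
double-center, eigen-decompose, and keep positive-eigenvalue axes scaled by
$\sqrt{\lambda}$. dbRDA computes $R^2$ as constrained over total inertia of
the principal coordinates (negative axes discarded — no Lingoes/Cailliez
correction) and adjusts by Ezekiel's formula. The three-way partition
(soil, climate, space) is assembled by inclusion–exclusion from the seven
subset models and reconstructs the full-model adjusted $R^2$ exactly; pure
fractions may be slightly negative and should then be read as zero.

Forward selection uses the double stopping rule: a candidate enters only
while its marginal permutation p-value is below $\alpha$ *and* the
cumulative adjusted $R^2$ stays at or below the full candidate model's.
Users should know a structural property of this rule (shared with
`vegan::ordiR2step`, which reproduces our selections exactly on identical
data): because the Ezekiel adjustment is unbiased, adding pure-noise
candidates leaves the *expected* adjusted $R^2$ unchanged, so when exactly
one candidate is real, the comparison "single-variable model vs full
model" is a near coin flip and the procedure returns an empty set in
roughly half of such datasets. With realistically inter-correlated
candidate panels the ceiling binds rarely. We keep the documented rule
rather than invent a modified one; the behavior is asserted in the test
suite.

## TITAN thresholds

Per taxon, every candidate split of the gradient (leaving at least
`min_side` samples per side) is scored by the group-equalized
Dufrêne–Legendre indicator value on relative abundances, scaled to
$[0, 100]$. The observed statistic is the maximum IndVal over candidates;
its z-score and p-value come from gradient permutations of the *same*
max-statistic, which makes the permutation p exactly uniform under the
null (ties are counted in full; the observed change point is the split
value, i.e. the last gradient value of the lower group, so a hard step at
$x_0$ is reported at the candidate immediately below $x_0$). Bootstrap
resampling of samples gives purity (direction agreement) and reliability
(bootstrap permutation $p \le 0.05$); taxa pass the filter at purity and
reliability $\ge 0.95$. Community thresholds tally the filtered taxa's
z-scores at their observed change points, by direction; the sum(z−) and
sum(z+) peaks are the lower and upper community change points.

## Co-occurrence networks

Edges are scored by Spearman correlation and Bray–Curtis similarity of
taxon profiles. Significance follows the ReBoot scheme: permutations
shuffle one taxon across samples and renormalize each sample's composition
(softening compositional coupling), bootstraps resample samples, and the
two-sided p-value is the Gaussian tail of the permutation null mean under
the bootstrap distribution $N(\mu_b, \sigma_b)$. The two measures'
p-values are combined by Brown's method — $X = -2(\ln p_1 + \ln p_2)$
referred to $c\,\chi^2_f$ with $c = \mathrm{Var}/(2\mathbb E)$,
$f = 2\mathbb E^2/\mathrm{Var}$, $\mathrm{Var} = 8 + 2\,\widehat{\mathrm{cov}}$
estimated empirically across candidate edges — then BH-adjusted. Edges
need $q \le 0.05$ and $|\rho|$ at or above the random-matrix-theory
threshold: the lowest scanned cutoff at which the unfolded adjacency
spectrum's nearest-neighbor spacings fit Poisson statistics
(χ², 20 bins on $[0,3]$) and keep fitting at all higher cutoffs.

Negative edges are kept in the graph (their counts and signs reported) but
excluded from fast-greedy module detection, which requires non-negative
weights; modularity is computed on the positive-edge subgraph. Dominant
modules (> 10% of nodes) are summarized by their eigengene — PC1 of the
z-scored member profiles, sign-anchored to the mean member abundance — and
correlated with environmental variables by Spearman. Local (per-sample)
networks are induced subgraphs on the taxa present in a sample; their
graph-level features, filtered for collinearity at $|\rho| > 0.7$ and
standardized, yield the Euclidean topology distances used in the spatial
regression and two-stage MRM.

## Numerical conventions

* Permutation p-values use $(1 + \#\mathrm{exceedances})/(1 + n_\mathrm{perm})$,
  never 0; Raup–Crick ties count half.
* Sturges' rule sets correlogram classes; Holm correction across classes.
* The Sloan fit optimizes $m \in (10^{-6}, 1]$ by Brent search; detection
  limit $d = 1/N$.
* Rarefaction is multivariate-hypergeometric (without replacement), seeded.
* Degenerate cases are flagged, not fatal: βNTI null sd $< 10^{-12}$,
  constant ReBoot profiles ($p = 1$), empty forward-selection sets,
  networks with no qualifying edges (error with message).
* NMDS uses 20 random restarts (`vegan::metaMDS`); envfit key variables
  need $R^2 > 0.2$ and $p < 0.01$ after discarding collinear variables at
  $|\rho_{\mathrm{Spearman}}| > 0.7$.

## Problem sizes used in validation

The test suite exercises the stack at desk scale, chosen to keep the full
run within minutes while leaving every comparison statistically meaningful:
oracle equivalences on 4–7 element problems against exhaustive
enumeration; parameter recovery at 100 sites × 300 taxa × 2000 reads
(Sloan), 40 samples × 30 taxa (TITAN, signal:noise ≈ 2), and 40 samples ×
40 taxa (block networks); regime discrimination at 40 sites × 300 taxa
with 999 null randomizations and ten seeded replicates per regime; and
calibration checks with 200 replicate p-values per statistic. The study
these sizes emulate rarefied 78 samples to ~18,600 (bacteria) and ~25,600
(fungi) reads over $10^4$ and $6 \times 10^3$ OTUs; all functions accept
such sizes, with βNTI/RC runtime scaling linearly in null count and
quadratically in sample number.

## Worked example

```{r example, eval = FALSE}
library(ecoassembly)

cfg <- simulation_config(n_sites = 40, n_taxa = 300,
                         reads_per_sample = 2000,
                         regime = "selection", seed = 7)
sim <- simulate_regime(cfg)

# preprocess as a survey would
tab <- filter_min_total_count(sim$table, 10)

# null-model process partitioning
ap <- assembly_processes(tab, sim$tree, n_null = 999, seed = 8)
ap$summary$fractions
ap$summary$sder_null

# neutral model
fit <- fit_sloan(tab)
fit

# variation partitioning
bc <- bray_curtis(tab)
sp <- as.data.frame(pcnm(geo_distance(sim$sites))$vectors)
vp <- variation_partition(bc,
                          sim$sites[c("pH", "OM", "TN", "TP", "TK", "AN")],
                          sim$sites[c("elevation", "MAT", "MAP")],
                          sp)
vp
```

## Known limitations

* βNTI assumes phylogenetic niche conservatism; run `phylo_signal()` first
  and distrust process fractions when the pretest fails.
* The Sloan *m* is a comparative index (see the recovery-bias section);
  its absolute value depends on the detection-limit convention.
* The SDER is unstable when the dispersal-limitation fraction approaches
  zero (ratio of small fractions); the package flags the infinite case
  rather than reporting a number.
* Forward selection's adjusted-$R^2$ ceiling is a coin flip against
  pure-noise candidate panels (see above).
* RMT thresholding needs enough taxa (≥ 30) and a largest component of
  ≥ 20 nodes per scanned cutoff; below that it falls back with a warning.
* The generator's dispersal-limitation signal weakens under strongly
  dominated regional pools, as described above.
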