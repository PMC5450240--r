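---
title: "Consensus network modules from gene-level GWAS scores: methods and design notes"
author: "gwasnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus network modules from gene-level GWAS scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasnet)
```

## The problem and the model

Genome-wide association studies rarely yield more than a handful of
genome-wide-significant genes, yet many true susceptibility genes sit just
below the significance threshold. `gwasnet` looks for them collectively: if
a connected set of genes in a protein-protein interaction (PPI) network is
jointly enriched in small association p-values, that subnetwork is a
candidate functional module even when no single member is significant on its
own.

The workflow has four stages.

**1. Gene-level association.** Per-SNP p-values (from an additive linear
model, `snp_association()`) are aggregated per gene as the sum of 1-df
chi-square quantiles,

$$Q_g = \sum_{s \in g} F^{-1}_{\chi^2_1}(1 - p_s),$$

and referred to a null obtained by simulating multivariate-normal vectors
with the SNPs' linkage-disequilibrium (LD) correlation matrix and summing
their squares (`adaptive_gene_test()`). Simulation effort is adaptive:
$10^3$ draws for every gene, $10^4$ for genes with running p ≤ 0.1, $10^6$
for genes with running p ≤ 0.001; an empty upper tail at the final stage is
reported as p below one over the simulation count. This keeps genome-scale
runs affordable while giving small p-values enough resolution to be compared
against a Bonferroni threshold (`bonferroni_threshold()`).

**2. Network smoothing.** Genes with p ≤ 0.05 (inclusive) are *seeds*. Each
PPI edge $(i,j)$ is weighted $W_{ij} = ((1-p_i) + (1-p_j))/2$, the weighted
adjacency matrix is normalized by columns, and a random walk with restart

$$P(t) = (1 - r)\,W_{\mathrm{norm}} P(t-1) + r P(0), \qquad
P(0)_i = \mathbf{1}[i \text{ is a seed}]$$

is iterated for a fixed number of steps. $P(T)$ is the vector of *node
weights*: each gene's topological proximity to the seed set.

**3. Module scoring and search.** A gene set $A$ scores

$$Z_A = \frac{\sum_{i \in A} P(T)_i z_i}{\sqrt{\sum_{i \in A} P(T)_i^2}},
\qquad z_i = \Phi^{-1}(1 - p_i),$$

a node-weight-weighted Liptak–Stouffer combination, standardized against
random gene sets of the same size: $S_A = (Z_A - \mu_k)/\sigma_k$ with
$(\mu_k, \sigma_k)$ estimated from `n_draws` uniform draws per size
(`calibrate_background()`). A greedy search grows one module from every
seed gene and keeps modules with $S$ above a cutoff and size within bounds
(`search_run()`).

**4. Consensus.** Because each run's background calibration and start order
are stochastic, the search is repeated under several RNG seeds. The top
subnetwork $TN_a$ of run $a$ is matched to its most Dice-similar subnetwork
$SN_b(TN_a)$ in every other run, and the consensus module is the
intersection

$$CM_a = TN_a \cap \bigcap_{b \neq a} SN_b(TN_a),$$

deduplicated across source runs; the intersection of all unique consensus
modules is the *common subnetwork* (`consensus_analysis()`). Modules are
annotated by one-sided Fisher exact pathway enrichment with
Benjamini–Hochberg adjustment, a rank-deviation z-score, and the combined
score $\ln(p_{\mathrm{adj}}) \cdot z$ (`enrich_query()`).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `seed_threshold` | 0.05 | gene p cutoff (inclusive) for seeds |
| `r` | 0.5 | restart probability of the walk |
| `steps` | 5 | walk iterations `T` (fixed, no convergence test) |
| `min_score` | 3.0 | adjusted score a module must exceed (strictly) |
| `min_size`, `max_size` | 5, 300 | module size bounds; `max_size` is also the background `k_max` |
| `bg_draws` | 1000 | random sets per size in the calibration |
| `seeds` | 1:10 | one search run per RNG seed |

The restart ratio is the most influential: larger `r` keeps mass on the
seeds, smaller `r` lets it diffuse to their neighborhoods. The defaults are
the standard operating point for this family of methods and are what the
test suite exercises.

## Design decisions in detail

**The probit convention for $z_i$.** The weighted-Z formula needs a
per-gene z. We use $z_i = \Phi^{-1}(1-p_i)$ — the classical one-sided
Liptak–Stouffer convention — so that smaller p means larger z and
significance-enriched sets get large $Z_A$. P-values are clamped to
$[10^{-15}, 1-10^{-15}]$ before inversion so z stays finite.

**Background sets are uniform, not connected.** Calibration draws gene sets
uniformly at random without a connectivity requirement. This makes
$(\mu_k, \sigma_k)$ a property of the score distribution, not of the graph
topology, and is self-consistent: random sets standardized by their own
background have mean $S \approx 0$ and s.d. $\approx 1$ (asserted in the
test suite). The background is re-drawn inside every run from the run's
RNG; this is one of the two sources of between-run stochasticity (the other
is the shuffled start order). A shared-background mode
(`search_run(background = )`) exists for debugging and oracle comparisons.

**Greedy growth climbs the raw score; the adjusted score picks the size.**
The obvious rule — add a neighbor only when $S$ strictly increases — turns
out to be unusable: $\sigma_k$ rises steeply over the first few sizes, so
$S$ dips transiently even while a genuinely significant module is being
absorbed, and growth stalls after one or two genes. We therefore expand on
the raw $Z$ (strict improvement, which is monotone along an enriched
module), record $S$ at every prefix of the growth path, and return the
smallest prefix whose $S$ is within one Monte-Carlo standard error of the
path maximum. The standard error uses the delta method,
$\mathrm{se}^2(S) \approx (1 + S^2/2)/n_{\mathrm{draws}}$, reflecting that
$\mu_k$ and $\sigma_k$ are themselves estimates: prefixes whose $S$ differ
by less than the calibration noise are indistinguishable, and the smaller
module is the more parsimonious call. Ties among candidate neighbors are
broken by smaller gene p, then lexicographic symbol, so growth is fully
deterministic given the run seed.

**Network restriction.** The working graph is the induced subgraph on genes
that have a gene-level p-value; the number of discarded nodes is logged.
Edge weights are undefined for unscored genes, and mapping a fraction of
the interactome is the normal situation with real PPI sources. $P(0)$ is
left exactly at 1 on seeds and 0 elsewhere — $Z_A$ is invariant to uniform
rescaling of the node weights (asserted numerically to $10^{-10}$), so
normalizing $P(0)$ would change nothing downstream.

**Consensus from top subnetworks only.** Only the top subnetwork of each
run seeds a consensus module; Dice ties during matching are resolved toward
the candidate with better rank (higher $S$), then the lexicographically
smallest gene set. Consensus modules are deduplicated on exact gene-set
equality; near-identical modules are reported separately rather than
merged.

**Enrichment conventions.** The default background universe is the working
network's gene set. The adjustment is Benjamini–Hochberg step-up, and the
combined score multiplies the log of the *adjusted* p by the rank z-score:
with these conventions the three statistics columns of a typical enrichment
report are mutually consistent (the tied-adjusted-p pattern of BH and the
combined scores are checked in the test suite). $p_{\mathrm{adj}}$ is
clamped at $10^{-300}$ before the logarithm.

## What the synthetic generators emulate — and what they do not

`generate_network()` builds a preferential-attachment graph: each incoming
node attaches `edges_per_node` edges to earlier nodes with probability
proportional to degree, giving exactly $(n-m)\,m$ edges, guaranteed
connectivity, and the heavy-tailed degree distribution that stresses the
column normalization and the walk the way a real interactome does. It does
not reproduce the clustering coefficient, the cliquishness of protein
complexes, or literature-curation ascertainment bias of real PPI databases.

`plant_module()` selects a connected ground-truth subgraph by a seeded
random walk (a breadth-first ball would produce degenerate stars around a
hub) and assigns planted genes p-values from a low-p uniform range and
background genes from U(0,1). `simulate_genotypes()` produces LD-blocked
dosages by thresholding AR(1) Gaussian haplotypes at MAF-matched quantiles;
blocks are independent, there is no recombination gradient, no population
structure, and no genotyping-platform artifacts. Consequently, a passing
benchmark demonstrates that the machinery recovers a coherent, strongly
enriched module against a uniform background — it does not certify
performance on real cohorts, where signal is weaker, LD extends across gene
boundaries, and the interactome is biased.

The benchmark sizes used by the tests and the acceptance script — a
600-node network with a 30-gene planted module, five runs, calibration to
`k_max` 60 with 200 draws per size; 200 three-SNP genes over 1000
individuals for the gene-test calibration — are the package's desk-scale
profile: large enough for stable behavior, small enough to run in seconds.

## Numerical choices and degenerate inputs

* SNP p-values are clamped to $[10^{-15}, 1]$ before chi-square inversion;
  a SNP at p = 1 contributes exactly 0 to $Q_g$.
* The LD correlation matrix is repaired to positive semidefiniteness by
  eigenvalue clipping at $10^{-8}$; zero-variance SNPs get identity rows
  with a warning.
* The empirical tail count uses ≥ with no +1 correction, so an empty tail
  is an exact 0, reported as floored (`p < 1/n_sims`).
* A zero seed set is an error: propagation has nothing to smooth.
* Degenerate backgrounds ($\sigma_k = 0$, e.g. when all genes carry the same
  score, or when `k_max` equals the number of genes so every draw is the
  same set) are an error rather than a silent division.
* Isolated nodes have zero operator columns; walk mass on them leaks by
  design, and mass conservation holds whenever no seed is isolated.
* Missing dosages are mean-imputed per SNP in the association test by
  default (a drop-individuals mode exists); monomorphic SNPs are flagged and
  given p = 1.

## Known limitations

The S > 3 module cutoff does not control the family-wise rate of module
discovery when a few percent of genes are nominally significant purely by
chance: the greedy search optimizes over seed-harvesting connected sets
that the uniform random-set background never resembles, so with U(0,1)
gene p-values some runs report modules above the cutoff. This is inherent
to the score's design, and it is exactly why the consensus step exists —
chance modules are unstable across runs, and intersecting each run's top
subnetwork with its best matches elsewhere strips unreplicated genes. When
no gene is nominally significant at all, there are no seeds and the
pipeline (correctly) refuses to run. Interpretation of any single-run
module list should therefore lean on replication across seeds, not on the
S cutoff alone.

The gene-based test inherits the usual caveats of simulation-based
aggregation: with the LD-free identity approximation (no genotypes
supplied) its p-values are conservative for genes in strong LD, and
flooring limits resolution to one over the final-stage simulation count.

## A minimal session

```{r example, message = FALSE, warning = FALSE}
g <- generate_network(400, 2, seed = 11)
pl <- plant_module(g, 20, seed = 11)
res <- run_pipeline(g, pl$scores, seeds = 1:3,
                    params = search_params(min_score = 3, min_size = 5,
                                           max_size = 40, bg_draws = 200))
res
recovery_metrics(res$consensus$unique_cms[[1]]$genes, pl$truth)
```
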