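---
title: "Clustering power and ploidy bias in mixed-ploidy populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering power and ploidy bias in mixed-ploidy populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clustering methods are the standard first look at population structure.
When a sample mixes cytotypes — here diploids and autotetraploids of the
same species — the two ploidy levels cannot be genotyped with equal
precision: a tetraploid marker phenotype "AB" is compatible with the three
genotypes AAAB, AABB and ABBB, and a dominant (AFLP-style) band hides the
allele count entirely. Under Hardy–Weinberg proportions a band is absent at
frequency $q^2$ in diploids but $q^4$ in tetraploids, so information loss is
*systematically different* between cytotypes. A clustering method that
estimates allele frequencies naively can therefore split a sample by ploidy
even when the cytotypes are drawn from one and the same gene pool — a pure
artefact.

`ploidyclust` provides a controlled test bed for this artefact:

1. a forward-time simulator of two mixed-ploidy populations whose cytotypes
   share one gene pool by construction (so *any* clustering by ploidy is
   bias);
2. the marker-encoding transforms that successively discard genotype
   information (known dosage → unknown dosage → dominant, plus two
   diploidizing subsampling transforms);
3. two clustering engines at $k = 2$: plain k-means on within-individual
   allele frequencies, and a Bayesian admixture Gibbs sampler whose data
   augmentation models the dosage uncertainty instead of guessing it;
4. the $\beta$-statistic pair that separates correct clustering
   ($\beta_{pop}$) from ploidy bias ($\beta_{ploidy}$).

## The simulation model

Each of two demes holds 500 diploids and 500 autotetraploids, i.e.
$500 \cdot 2 + 500 \cdot 4 = 3000$ copies of the haploid genome. The state
is the count of allele A per locus per deme ($0 \dots 3000$); loci are
unlinked, biallelic and neutral. Per generation, in this order:

* **mutation** (reversible, rate $u$ per copy): $p \mapsto p(1-u) + (1-p)u$;
* **migration** (rate $m$, from the other deme, synchronously):
  $p_i \mapsto (1-m)p_i + m p_j$;
* **drift**: the new count is $\mathrm{Binomial}(3000, p)$.

Runs last 100,000 generations, far beyond the mutation–migration–drift
equilibration time (the slowest relaxation scale is of order
$1/(4m + 2u)$ generations, well under 10,000 for every rate used). The
initial frequency is 0.5 at every locus in both demes; the initial
condition is forgotten long before sampling, and starting at 0.5 avoids
spending most of the run recovering from early mass fixation. Both demes
update from the same pre-update snapshot (synchronous update); sequential
updating changes the pairwise decay factor from $(1-2m)$ to $(1-m)^2$,
which is identical to first order, so nothing measurable depends on this
choice.

The model is deliberately minimal: no individuals, no linkage, no
selection, no double reduction, no reproductive barrier between cytotypes,
random mating including selfing. Minimality is the point — because
cytotypes are sampled from the same allele-frequency vector, a clustering
split along ploidy cannot reflect real differentiation.

Defaults (all exposed in `sim_params()`): $u = 10^{-4}$ (giving
within-deme gene diversity around 0.35, a realistic SNP panel), $m$ from
0.1 down to 0.001, $l = 100$ loci, 100,000 generations.

## Measuring differentiation

`multilocus_fst()` works from the true deme allele frequencies, pooling
loci as ratios of sums so near-monomorphic loci cannot destabilise the
estimate, and a state with *no* polymorphic locus returns `NA` with a
warning rather than a silent 0.

Two variants are available. Raw Nei $G_{st} = \sum(H_T - H_S)/\sum H_T$ is
the textbook quantity, but with only $k = 2$ demes and diversity
$H_S \approx 0.35$ it is doubly compressed: $H_T$ can exceed $H_S$ by at
most a factor tied to the between-deme variance share for two demes, and
its maximum attainable value is far below 1. The default is therefore the
standardized measure
$$F''_{st} = \frac{k\,(H_T - H_S)}{(k H_T - H_S)(1 - H_S)},$$
which corrects for both the small number of demes and the diversity
ceiling and puts the migration sweep on the familiar $F_{st}$ scale: the
acceptance script computes replicate means of roughly 0.013 at $m = 0.01$
and 0.10–0.11 at $m = 0.001$, and a sweep maximum near 0.11 — the 0 to
0.15 range the scenario presets are designed to cover. The raw variant remains
available via `standardized = FALSE`, and the exactly known small cases
(e.g. $G_{st} = 0.36$ for frequencies 0.2 vs 0.8 at a single locus) are
pinned in the unit tests.

## Genotype sampling and encodings

`sample_genotypes()` draws each individual's dosage as
$\mathrm{Binomial}(\text{ploidy}, p_{deme})$ — sampling with replacement
from the 3000-copy pool, indistinguishable from without-replacement draws
at sample sizes of a few hundred. The encodings:

| encoding | tetraploid entry | diploid entry |
|---|---|---|
| `known_dosage` | dosage 0–4 | dosage 0–2 |
| `unknown_dosage` | 0, 4, or `AMBIGUOUS` for 1–3 | unchanged |
| `dominant` | 1 if dosage ≥ 1 else 0 | same rule |
| `diploidized_known` | 2 of 4 copies drawn without replacement | unchanged |
| `diploidized_unknown` | het → 1, 0 → 0, 4 → 2 | unchanged |

`AMBIGUOUS` is a sentinel (`-1L`), deliberately distinct from missing data
(`NA`): "phenotype AB, dosage unknown" carries information that "no data"
does not, and the Bayesian engine uses it.

## The clustering engines

**k-means** (`km_cluster()`): Lloyd's algorithm on the within-individual
allele-frequency matrix, values $\{0, \tfrac12, 1\}$ for diploids and
$\{0, \tfrac14, \tfrac12, \tfrac34, 1\}$ for tetraploids. Ambiguous
entries are coded 0.5 — the expectation under a uniform dosage guess and
the midpoint of the compatible values; it is exactly this one-number
summary of a three-genotype ambiguity that manufactures ploidy-structured
columns and lets the bias emerge. No PCA step precedes the clustering and
columns are not rescaled (allele-frequency columns share a scale already).
Numerical choices: 50 random restarts, centroids initialised from distinct
data rows, at most 300 sweeps, convergence when assignments stop changing,
an emptied cluster re-seeded at the point farthest from its centroid, and
ties in the best-of-restarts comparison resolved toward the earlier
restart. On small instances the achieved within-cluster sum of squares is
tested equal to the exhaustive optimum over all 2-partitions.

**Bayesian admixture** (`bayes_cluster()`): the admixture model with
uncorrelated allele frequencies at fixed $k$. Latent variables: the
cluster-of-origin $z$ of every allele copy and — wherever the encoding
hides it — the dosage $d$ itself. Per sweep, $(d, z)$ are resampled
jointly by enumerating the phenotype-legal dosages
(`phenotype_legal_dosages()`: {1,2,3} for an ambiguous tetraploid,
{1..ploidy} for a dominant presence, {0} for an absence), with
$P(d) \propto \binom{pl}{d} x^d (1-x)^{pl-d}$ restricted to the legal set,
where $x$ is the individual's admixture-weighted allele frequency; cluster
frequencies get conjugate $\mathrm{Beta}(\lambda + n_A, \lambda + n_B)$
updates with $\lambda = 1$, admixture rows conjugate Dirichlet updates,
and the concentration $\alpha$ a Metropolis step (uniform prior on
$(0, 10]$, proposal SD 0.05, initial value 1). Because the ambiguity is
integrated over rather than point-imputed, the engine has no mechanism to
prefer a split by ploidy — which is precisely what the benchmark verifies.

Chains: defaults of 10,000 burn-in + 100,000 recorded sweeps and ten
replicate chains mirror common practice for samplers of this family; the
scenario runner and the acceptance tests use 2,000 + 10,000 with three
chains after spot checks showed indistinguishable posterior means on these
data sizes (the model is unimodal up to label swap at $k=2$ with this much
data per individual). The replicate with the highest *mean* post-burn-in
data log-likelihood is kept — the mean is stabler than the final value —
with ties broken toward the lower replicate index. Missing genotypes are
skipped in every update and in the likelihood. The hot loop is compiled
(Rcpp) but consumes R's RNG, so runs are reproducible from `set.seed()`
alike for the compiled and the pure-R reference implementation, which are
cross-checked against each other in the tests.

Label switching needs no handling anywhere: the $\beta$-statistic is
invariant to swapping the clusters.

## The β-statistic

For membership proportions $q_1$ (column 1 of the membership matrix) and a
binary grouping, $\beta$ is the absolute difference of the two group means
of $q_1$ — algebraically identical to the absolute slope of the
least-squares regression of $q_1$ on the 0/1 group indicator, an identity
`evaluate_clustering()` re-verifies numerically on every call (and the
tests verify against `lm()` on random inputs). $\beta_{pop}$ uses the deme
labels, $\beta_{ploidy}$ the cytotype labels. In the balanced crossed
design used throughout, $\beta_{pop} + \beta_{ploidy} \le 1$, so perfect
clustering by population and by ploidy are mutually exclusive outcomes;
the sum bound is property-tested with random memberships. Hard clusterings
enter as one-hot rows (a group mean of 0/1 indicators is just the assigned
proportion), so one formula serves both engines.

## Scenario presets and problem sizes

`builtin_specs()` carries the benchmark designs: `default` (eight
migration rates 0.001–0.1, 100 loci, 400 individuals — 100 diploids and
100 tetraploids per deme), `low_mutation` ($u = 10^{-5}$), two
loci-versus-individuals grids (`tradeoff_weak`, `tradeoff_strong`: loci
10–1000 × individuals 40–400 at $m = 0.01$ and $0.001$), and `gbs`
(40 individuals × 10,000 loci, no dominant encoding — dominant GBS panels
do not occur in practice). The exact spacing of the eight-rate sweep is a
package choice (log-spaced); pass any custom vector to override it.

Everything derives from one master seed: each grid cell draws its
simulation, sampling, encoding and clustering streams from seeds derived
once up front, so `run_scenario()` is reproducible row for row.

The acceptance-scale runs in `tests/testthat/test-acceptance.R` use full
100,000-generation simulations throughout (the compiled loop makes them
cheap); the bias check runs 120 sampled individuals × 100 loci (the bias
grows with loci, not individuals, so the smaller sample loses nothing),
while the power check keeps the full 400-individual design, where the
Bayesian posterior is sharpest. Five simulation replicates per check, MCMC
at 2,000 + 10,000 × 3 chains.

## What the generator does and does not emulate

It emulates: drift–migration–mutation equilibrium in two connected demes,
realistic SNP-panel diversity, balanced mixed-ploidy sampling, and the
three marker information levels practitioners actually face. It does not
emulate: genotyping error or undercalling (heterozygotes read as
homozygotes at low depth), linkage, selection, inbreeding structure,
unequal sample sizes, more than two demes or cytotypes, or any real
divergence between cytotypes. Passing tests therefore demonstrate the
*mechanism* of ploidy bias and its removal by dosage-aware modelling —
they do not certify behaviour on real data with error, linkage or
cytotype divergence, and with unequal group sizes the
$\beta_{pop} + \beta_{ploidy} \le 1$ bound no longer holds.

## Worked example

```{r}
library(ploidyclust)

sim <- run_simulation(sim_params(n_loci = 100, migration_rate = 0.1,
                                 seed = 11))
multilocus_fst(sim)        # ~0.001: essentially no real structure

G <- sample_genotypes(sim, sample_design(30), seed = 12)  # 120 individuals
D <- encode_dominant(G)

evaluate_clustering(km_cluster(D, seed = 13), G$deme, G$ploidy)
# beta_pop ~ 0.02, beta_ploidy ~ 0.9: k-means invents clusters = cytotypes

fit <- bayes_cluster(D, k = 2,
                     mcmc_settings(burnin = 2000, iterations = 10000,
                                   replicates = 3, seed = 14))
evaluate_clustering(fit, G$deme, G$ploidy)
# beta_pop ~ 0.02, beta_ploidy ~ 0.01: the dosage-aware sampler stays flat
```

## Known limitations

* Two demes and two ploidy levels are hard-wired in the simulator's
  surface (the internals would generalise, but no more is implemented or
  tested).
* The Bayesian engine implements only the uncorrelated-frequencies
  admixture model; no correlated-frequencies F-model, no linkage model, no
  inference of $k$, no inbreeding estimation.
* `multilocus_fst()` describes the simulated populations from their true
  frequencies; it is not a sample-based estimator for empirical datasets.
* The Structure-style file dialect is this package's own (documented in
  `?write_structure_file` and frozen by golden-file tests); round-tripping
  is guaranteed only for files this package wrote.
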