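# ploidyclust

Clustering power and ploidy bias in simulated mixed-ploidy populations.

Population-structure clustering is routinely applied to samples that mix
diploids and autotetraploids. The cytotypes cannot be genotyped with equal
precision — a tetraploid phenotype "AB" is compatible with AAAB, AABB and
ABBB, and a dominant (AFLP-style) band hides allele counts entirely; under
Hardy–Weinberg a band is absent at frequency *q*² in diploids but *q*⁴ in
tetraploids. Methods that estimate allele frequencies naively can therefore
cluster a sample *by ploidy* even when both cytotypes are drawn from one
gene pool. `ploidyclust` is a test bed that quantifies this artefact and
shows how dosage-aware modelling removes it.

The package provides:

* **`run_simulation()`** — forward-time allele-frequency simulation of two
  demes, each with 500 diploids + 500 autotetraploids (3000 genome copies),
  reversible mutation at rate *u*, symmetric migration at rate *m*,
  binomial drift, 100,000 generations to mutation–migration–drift
  equilibrium (compiled inner loop, seed-reproducible).
* **`sample_genotypes()` / `encode_genotypes()`** — mixed-ploidy genotype
  matrices under five information levels: known dosage, unknown dosage
  (ambiguous tetraploid heterozygotes), dominant presence/absence, and two
  diploidizing transforms; plus Structure-style, PLINK-style and TSV
  writers.
* **`km_cluster()`** — k-means (Lloyd, multi-start) on the matrix of
  within-individual allele frequencies.
* **`bayes_cluster()`** — a Gibbs sampler for the admixture model with
  uncorrelated allele frequencies, extended with ploidy-aware data
  augmentation: latent dosages are resampled jointly with per-copy cluster
  origins over the phenotype-legal dosage sets, so unknown dosage and
  dominant data are modelled rather than guessed.
* **`beta_statistic()` / `evaluate_clustering()`** — the β-pair at k = 2:
  β_pop = |difference in mean assignment between demes| (correct
  clustering), β_ploidy = the same across cytotypes (bias). Both equal the
  absolute slope of the 0/1-coded least-squares regression, are invariant
  to cluster relabeling, and satisfy β_pop + β_ploidy ≤ 1 in the balanced
  design.
* **`run_scenario()` / `builtin_specs()`** — end-to-end benchmark grids:
  the eight-rate migration sweep, loci × individuals trade-offs, and a
  genotyping-by-sequencing design (40 individuals × 10,000 loci).

A thin command-line front end lives in `exec/ploidyclust`
(`simulate` / `encode` / `cluster` / `run` subcommands).

## Worked example

The signature result in a few lines — at migration rate m = 0.1 the two
demes are effectively panmictic (no real structure), yet k-means on
dominant markers clusters almost perfectly by cytotype, while the
dosage-aware Bayesian engine finds nothing, exactly as it should:

```r
library(ploidyclust)

sim <- run_simulation(sim_params(n_loci = 100, migration_rate = 0.1, seed = 11))
multilocus_fst(sim)
#> [1] 0.001197106

G <- sample_genotypes(sim, sample_design(30), seed = 12)   # 120 individuals
D <- encode_dominant(G)

evaluate_clustering(km_cluster(D, seed = 13), G$deme, G$ploidy)
#> beta_pop = 0.017 (correct clustering by population)
#> beta_ploidy = 0.917 (spurious clustering by ploidy)

fit <- bayes_cluster(D, k = 2, mcmc_settings(burnin = 2000, iterations = 10000,
                                             replicates = 3, seed = 14))
evaluate_clustering(fit, G$deme, G$ploidy)
#> beta_pop = 0.020 (correct clustering by population)
#> beta_ploidy = 0.011 (spurious clustering by ploidy)
```

β_ploidy ≈ 0.92 means k-means put nearly every diploid in one cluster and
nearly every tetraploid in the other — pure artefact, since both cytotypes
were sampled from the same allele frequencies. The Bayesian sampler, which
integrates over the dosages compatible with each band, reports essentially
no structure of either kind.

At strong differentiation (m = 0.001, F_st ≈ 0.11) both engines recover
the two demes with β_pop > 0.9 on co-dominant data with known dosage.

See `vignettes/mixed-ploidy-clustering.Rmd` for the model, the sampler,
all tunable parameters and the design decisions.

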