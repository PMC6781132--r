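# Small fixtures shared across test files; everything is built in code.

# A genotype matrix with explicit dosages: half diploid, half tetraploid,
# split over two demes.
toy_genotypes <- function(dosage, ploidy, deme) {
  ploidyclust:::new_genotype_matrix(dosage, ploidy, deme)
}

# Two well-separated demes, mixed ploidy, built from fixed allele
# frequencies (no forward simulation needed).
make_structured_genotypes <- function(n_per_group = 5L, n_loci = 20L,
                                      p1 = 0.05, p2 = 0.95, seed = 1L) {
  set.seed(seed)
  ploidy <- rep(c(2L, 4L, 2L, 4L), each = n_per_group)
  deme <- rep(c(1L, 2L), each = 2L * n_per_group)
  p <- ifelse(deme == 1L, p1, p2)
  dosage <- matrix(0L, length(ploidy), n_loci)
  for (i in seq_along(ploidy)) {
    dosage[i, ] <- stats::rbinom(n_loci, ploidy[i], p[i])
  }
  toy_genotypes(dosage, ploidy, deme)
}

# A small allele-count state at chosen frequencies, for sampling tests.
state_at_freqs <- function(freqs, n_dip = 500L, n_tet = 500L) {
  params <- sim_params(n_loci = length(freqs), migration_rate = 0.01,
                       n_diploids_per_deme = n_dip,
                       n_tetraploids_per_deme = n_tet, n_generations = 0L)
  counts <- rbind(round(freqs * params$copies_per_deme),
                  round(freqs * params$copies_per_deme))
  storage.mode(counts) <- "integer"
  st <- ploidyclust:::new_allele_count_state(counts, params, 0L)
  class(st) <- c("ploidy_sim", class(st))
  st
}

# Exhaustive best 2-partition total within-cluster sum of squares.
brute_force_best_ss <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {  # fix individual n in cluster 2
    grp <- as.integer(intToBits(mask))[1:n] == 1L
    ss <- 0
    for (g in c(TRUE, FALSE)) {
      xs <- x[grp == g, , drop = FALSE]
      if (nrow(xs) == 0L) { ss <- Inf; break }
      ctr <- colMeans(xs)
      ss <- ss + sum(sweep(xs, 2L, ctr)^2)
    }
    if (ss < best) best <- ss
  }
  best
}
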