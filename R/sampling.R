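#' Sentinel for an ambiguous tetraploid dosage
#'
#' Marks a tetraploid heterozygote whose allele dosage is unknown (the
#' marker phenotype "AB", compatible with genotypes AAAB, AABB and ABBB).
#' Distinct from missing data, which is `NA`.
#' @export
AMBIGUOUS <- -1L

#' Sampling design for genotype construction
#'
#' The study design samples `n` diploids and `n` tetraploids from each of
#' the two demes, i.e. `4 n` individuals in total (400 with the default
#' `n = 100`).
#'
#' @param n_per_ploidy_per_deme individuals sampled per cytotype per deme.
#' @return a `sample_design` list with the derived `total_individuals`.
#' @export
sample_design <- function(n_per_ploidy_per_deme = 100L) {
  stopifnot(n_per_ploidy_per_deme >= 1)
  structure(
    list(n_per_ploidy_per_deme = as.integer(n_per_ploidy_per_deme),
         total_individuals = 4L * as.integer(n_per_ploidy_per_deme)),
    class = "sample_design"
  )
}

new_genotype_matrix <- function(dosage, ploidy, deme) {
  stopifnot(is.matrix(dosage), nrow(dosage) == length(ploidy),
            length(ploidy) == length(deme),
            all(ploidy %in% c(2L, 4L)), all(deme %in% c(1L, 2L)))
  ok <- dosage >= 0 & dosage <= ploidy
  if (!all(ok[!is.na(dosage)])) stop("dosage outside [0, ploidy]")
  structure(
    list(dosage = dosage, ploidy = as.integer(ploidy),
         deme = as.integer(deme)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d loci\n",
              nrow(x$dosage), ncol(x$dosage)))
  tab <- table(deme = x$deme, ploidy = x$ploidy)
  print(tab)
  invisible(x)
}

#' Sample individual genotypes from the final allele-frequency state
#'
#' For each sampled individual the allele-A dosage at a locus is drawn as
#' `Binomial(ploidy, p)` with `p` the deme's allele frequency in the final
#' generation: diploids and tetraploids are drawn from the same gene pool,
#' so by construction there is no divergence between cytotypes — any
#' clustering by ploidy downstream is bias, not signal. Sampling is with
#' replacement from the copy pool; with samples far smaller than the
#' 3000-copy pool this is indistinguishable from without-replacement draws.
#'
#' @param state a `ploidy_sim` / `allele_count_state`.
#' @param design a [sample_design()].
#' @param seed optional seed.
#' @return a `genotype_matrix`: integer dosage matrix (individuals x loci)
#'   plus per-individual `ploidy` (2 or 4) and `deme` (1 or 2) labels.
#'   Row order: deme 1 diploids, deme 1 tetraploids, deme 2 diploids,
#'   deme 2 tetraploids.
#' @export
sample_genotypes <- function(state, design = sample_design(), seed = NULL) {
  params <- state$params
  n <- design$n_per_ploidy_per_deme
  if (n > params$n_diploids_per_deme || n > params$n_tetraploids_per_deme)
    stop("sampling design exceeds the simulated population size")
  if (!is.null(seed)) set.seed(seed)
  p <- allele_freqs(state)
  L <- ncol(p)
  blocks <- list()
  ploidy <- integer(0)
  deme <- integer(0)
  for (d in 1:2) {
    for (pl in c(2L, 4L)) {
      blk <- matrix(
        stats::rbinom(n * L, size = pl, prob = rep(p[d, ], each = n)),
        nrow = n, ncol = L
      )
      blocks[[length(blocks) + 1L]] <- blk
      ploidy <- c(ploidy, rep(pl, n))
      deme <- c(deme, rep(d, n))
    }
  }
  dosage <- do.call(rbind, blocks)
  rownames(dosage) <- sprintf("ind_%03d", seq_len(nrow(dosage)))
  colnames(dosage) <- sprintf("L%03d", seq_len(L))
  new_genotype_matrix(dosage, ploidy, deme)
}

new_encoded_dataset <- function(values, ploidy, deme, encoding) {
  structure(
    list(values = values, ploidy = as.integer(ploidy),
         deme = as.integer(deme), encoding = encoding),
    class = "encoded_dataset"
  )
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf("Encoded dataset (%s): %d individuals x %d loci\n",
              x$encoding, nrow(x$values), ncol(x$values)))
  if (x$encoding == "unknown_dosage") {
    n_amb <- sum(x$values == AMBIGUOUS, na.rm = TRUE)
    cat(sprintf("  %d ambiguous tetraploid heterozygote entries\n", n_amb))
  }
  invisible(x)
}

encodings <- function() {
  c("known_dosage", "unknown_dosage", "dominant",
    "diploidized_known", "diploidized_unknown")
}

#' Encode genotypes with full dosage information
#'
#' The co-dominant, known-dosage dataset: values are the allele-A dosages
#' unchanged.
#' @param G a `genotype_matrix`.
#' @return an `encoded_dataset` with `encoding = "known_dosage"`.
#' @export
encode_known_dosage <- function(G) {
  new_encoded_dataset(G$dosage, G$ploidy, G$deme, "known_dosage")
}

#' Encode genotypes with unknown tetraploid dosage
#'
#' Tetraploid heterozygotes lose their dosage: AAAB, AABB and ABBB all
#' collapse to the phenotype "AB", represented by the [AMBIGUOUS] sentinel.
#' Tetraploid homozygotes (dosage 0 or 4) and all diploid genotypes are
#' unchanged.
#' @param G a `genotype_matrix`.
#' @return an `encoded_dataset` with `encoding = "unknown_dosage"`.
#' @export
encode_unknown_dosage <- function(G) {
  v <- G$dosage
  tet <- G$ploidy == 4L
  het <- v >= 1L & v <= 3L
  v[tet & het] <- AMBIGUOUS
  new_encoded_dataset(v, G$ploidy, G$deme, "unknown_dosage")
}

#' Encode genotypes as dominant presence/absence markers
#'
#' Allele A is taken as dominant: the value is 1 when at least one A copy
#' is present (band presence, AFLP-style) and 0 otherwise, for every
#' ploidy. Under Hardy-Weinberg proportions band absence occurs at
#' frequency q^2 in diploids but q^4 in tetraploids (q the recessive-allele
#' frequency), which is the root of the ploidy bias the package measures.
#' @param G a `genotype_matrix`.
#' @return an `encoded_dataset` with `encoding = "dominant"`.
#' @export
encode_dominant <- function(G) {
  v <- G$dosage
  v[] <- as.integer(v >= 1L)
  new_encoded_dataset(v, G$ploidy, G$deme, "dominant")
}

#' Diploidize known-dosage genotypes by subsampling allele copies
#'
#' For each tetraploid entry two of the four allele copies are drawn
#' without replacement, so a dosage `a` maps to `Hypergeometric(4, a, 2)`;
#' diploid rows are unchanged. All rows in the result are declared diploid
#' — this is the subsampling transform used to feed mixed-ploidy data to
#' strictly diploid programs.
#' @param G a `genotype_matrix`.
#' @param seed optional seed for the subsampling draws.
#' @return an `encoded_dataset` with `encoding = "diploidized_known"` and
#'   all ploidies equal to 2.
#' @export
diploidize_known <- function(G, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- G$dosage
  tet <- which(G$ploidy == 4L)
  if (length(tet)) {
    sub <- v[tet, , drop = FALSE]
    # rhyper: white balls = A copies, black = B copies, draw 2
    sub[] <- stats::rhyper(length(sub), m = as.vector(sub),
                           n = 4L - as.vector(sub), k = 2L)
    v[tet, ] <- sub
  }
  new_encoded_dataset(v, rep(2L, length(G$ploidy)), G$deme,
                      "diploidized_known")
}

#' Diploidize unknown-dosage genotypes deterministically
#'
#' The phenotype-level collapse used when dosage is unknown: every
#' heterozygous tetraploid genotype becomes the diploid heterozygote AB
#' (dosage 1), homozygotes map to the corresponding diploid homozygote
#' (0 -> 0, 4 -> 2); diploid rows are unchanged.
#' @param G a `genotype_matrix`.
#' @return an `encoded_dataset` with `encoding = "diploidized_unknown"`.
#' @export
diploidize_unknown <- function(G) {
  v <- G$dosage
  tet <- G$ploidy == 4L
  het <- v >= 1L & v <= 3L
  v[tet & het] <- 1L
  v[tet & v == 4L] <- 2L
  new_encoded_dataset(v, rep(2L, length(G$ploidy)), G$deme,
                      "diploidized_unknown")
}

#' Apply an encoding by name
#'
#' @param G a `genotype_matrix`.
#' @param encoding one of `"known_dosage"`, `"unknown_dosage"`,
#'   `"dominant"`, `"diploidized_known"`, `"diploidized_unknown"`.
#' @param seed passed to [diploidize_known()] (the only stochastic
#'   transform).
#' @return an `encoded_dataset`.
#' @export
encode_genotypes <- function(G, encoding, seed = NULL) {
  encoding <- match.arg(encoding, encodings())
  switch(encoding,
    known_dosage = encode_known_dosage(G),
    unknown_dosage = encode_unknown_dosage(G),
    dominant = encode_dominant(G),
    diploidized_known = diploidize_known(G, seed = seed),
    diploidized_unknown = diploidize_unknown(G)
  )
}
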