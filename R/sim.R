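#' Simulation parameters for the two-deme mixed-ploidy model
#'
#' Bundles and validates the parameters of the forward-time allele-frequency
#' simulator: two populations (demes), each containing
#' `n_diploids_per_deme` diploids and `n_tetraploids_per_deme`
#' autotetraploids, so that every deme carries
#' `2 * n_diploids + 4 * n_tetraploids` copies of the haploid genome
#' (3000 with the defaults). Loci are unlinked and biallelic (alleles A/B),
#' mutation is reversible at rate `u` per copy per generation, and the demes
#' exchange migrants symmetrically at rate `m`.
#'
#' @param n_loci number of independent biallelic loci.
#' @param migration_rate per-copy probability `m` of originating from the
#'   other deme, applied to expected frequencies each generation.
#' @param mutation_rate per-copy reversible mutation probability `u`.
#' @param n_diploids_per_deme,n_tetraploids_per_deme census sizes per deme.
#' @param n_generations number of generations to iterate; the default
#'   100,000 is ample to reach mutation-migration-drift equilibrium.
#' @param initial_freq starting frequency of allele A at every locus in both
#'   demes. The default 0.5 avoids early mass fixation; after the default
#'   number of generations the initial condition is forgotten.
#' @param seed optional integer seed making the run reproducible.
#'
#' @return An object of class `sim_params` (a validated list). The element
#'   `copies_per_deme` is derived, never supplied.
#' @seealso [run_simulation()], [step_generation()]
#' @export
#' @examples
#' sim_params(n_loci = 10, migration_rate = 0.01)
sim_params <- function(n_loci = 100L,
                       migration_rate = 0.01,
                       mutation_rate = 1e-4,
                       n_diploids_per_deme = 500L,
                       n_tetraploids_per_deme = 500L,
                       n_generations = 100000L,
                       initial_freq = 0.5,
                       seed = NULL) {
  stopifnot(
    length(n_loci) == 1L, n_loci >= 1,
    n_diploids_per_deme >= 1, n_tetraploids_per_deme >= 1,
    n_generations >= 0
  )
  if (mutation_rate < 0 || mutation_rate > 0.5)
    stop("mutation_rate must lie in [0, 0.5]")
  if (migration_rate < 0 || migration_rate > 0.5)
    stop("migration_rate must lie in [0, 0.5]")
  if (initial_freq < 0 || initial_freq > 1)
    stop("initial_freq must lie in [0, 1]")
  p <- list(
    n_demes = 2L,
    n_diploids_per_deme = as.integer(n_diploids_per_deme),
    n_tetraploids_per_deme = as.integer(n_tetraploids_per_deme),
    copies_per_deme = as.integer(2L * n_diploids_per_deme +
                                   4L * n_tetraploids_per_deme),
    n_loci = as.integer(n_loci),
    mutation_rate = mutation_rate,
    migration_rate = migration_rate,
    n_generations = as.integer(n_generations),
    initial_freq = initial_freq,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Two-deme mixed-ploidy simulation parameters\n")
  cat(sprintf("  demes: %d x (%d diploids + %d tetraploids) = %d genome copies each\n",
              x$n_demes, x$n_diploids_per_deme, x$n_tetraploids_per_deme,
              x$copies_per_deme))
  cat(sprintf("  loci: %d   u = %g   m = %g   generations: %d\n",
              x$n_loci, x$mutation_rate, x$migration_rate, x$n_generations))
  invisible(x)
}

#' Expected allele frequency after one round of reversible mutation
#'
#' With reversible mutation at rate `u`, an allele-A frequency `p` moves to
#' `p (1 - u) + (1 - p) u` in expectation: a fraction `u` of A copies mutate
#' to B and a fraction `u` of B copies mutate back to A. At fixation
#' (`p = 1`) with `u = 1e-4` the expected frequency is 0.9999.
#'
#' @param p allele frequency in `[0, 1]` (vectorised).
#' @param u mutation rate in `[0, 0.5]`.
#' @return expected frequency, guaranteed within `[u, 1 - u]`.
#' @export
#' @examples
#' expected_freq_after_mutation(1, 1e-4)  # 0.9999
expected_freq_after_mutation <- function(p, u) {
  if (any(p < 0 | p > 1)) stop("allele frequency p must lie in [0, 1]")
  if (any(u < 0 | u > 0.5)) stop("mutation rate u must lie in [0, 0.5]")
  p * (1 - u) + (1 - p) * u
}

#' Expected allele frequency after migration from the other deme
#'
#' A fraction `m` of the gametes forming the next generation originate from
#' the other deme, so the expected frequency becomes
#' `(1 - m) p_focal + m p_other`. Applied after mutation, matching the
#' simulator's update order.
#'
#' @param p_focal post-mutation frequency in the focal deme (vectorised).
#' @param p_other post-mutation frequency in the other deme.
#' @param m migration rate in `[0, 0.5]`.
#' @return expected frequency in the focal deme.
#' @export
#' @examples
#' expected_freq_after_migration(1, 0, 0.1)  # 0.9
expected_freq_after_migration <- function(p_focal, p_other, m) {
  if (any(p_focal < 0 | p_focal > 1) || any(p_other < 0 | p_other > 1))
    stop("allele frequencies must lie in [0, 1]")
  if (any(m < 0 | m > 0.5)) stop("migration rate m must lie in [0, 0.5]")
  (1 - m) * p_focal + m * p_other
}

new_allele_count_state <- function(counts, params, generation = 0L) {
  stopifnot(is.matrix(counts), nrow(counts) == params$n_demes,
            ncol(counts) == params$n_loci)
  structure(
    list(counts = counts, generation = as.integer(generation),
         params = params),
    class = "allele_count_state"
  )
}

initial_state <- function(params) {
  cnt <- as.integer(round(params$initial_freq * params$copies_per_deme))
  counts <- matrix(cnt, nrow = params$n_demes, ncol = params$n_loci)
  new_allele_count_state(counts, params, 0L)
}

#' Advance the allele-count state by one generation
#'
#' For every deme and locus the expected allele-A frequency is computed by
#' applying mutation first and migration second (both demes read the same
#' pre-update snapshot, i.e. a synchronous update), and the new allele-copy
#' count is drawn as `Binomial(copies_per_deme, expected frequency)` — the
#' Wright-Fisher resampling of the 3000-copy gamete pool.
#'
#' @param state an `allele_count_state` as produced by [run_simulation()]
#'   (or internally).
#' @param params the matching [sim_params()].
#' @return a new `allele_count_state` with `generation` incremented.
#' @export
step_generation <- function(state, params = state$params) {
  p <- state$counts / params$copies_per_deme
  pm <- expected_freq_after_mutation(p, params$mutation_rate)
  m <- params$migration_rate
  # synchronous: both rows adjusted from the same post-mutation snapshot
  pe <- rbind(
    expected_freq_after_migration(pm[1L, ], pm[2L, ], m),
    expected_freq_after_migration(pm[2L, ], pm[1L, ], m)
  )
  counts <- matrix(
    stats::rbinom(length(pe), size = params$copies_per_deme, prob = pe),
    nrow = params$n_demes
  )
  new_allele_count_state(counts, params, state$generation + 1L)
}

#' Run the forward-time two-deme simulation to equilibrium
#'
#' Iterates [step_generation()] for `params$n_generations` generations from
#' an initial state where every locus sits at `params$initial_freq` in both
#' demes. With the default 100,000 generations the populations reach
#' mutation-migration-drift equilibrium, so the final state characterises
#' the stationary differentiation implied by `u` and `m`.
#'
#' @param params a [sim_params()] object.
#' @param engine `"cpp"` (compiled generation loop, the default) or `"r"`
#'   (iterated [step_generation()]). Both consume R's RNG in the same
#'   order, so a given seed yields the identical trajectory either way.
#' @return an object of class `ploidy_sim` (also `allele_count_state`)
#'   holding the integer allele-copy matrix (`n_demes x n_loci`), the
#'   generation counter and the parameters.
#' @export
#' @examples
#' sim <- run_simulation(sim_params(n_loci = 20, migration_rate = 0.01,
#'                                  n_generations = 500, seed = 1))
#' multilocus_fst(sim)
run_simulation <- function(params, engine = c("cpp", "r")) {
  stopifnot(inherits(params, "sim_params"))
  engine <- match.arg(engine)
  if (!is.null(params$seed)) set.seed(params$seed)
  state <- initial_state(params)
  if (engine == "cpp") {
    counts <- forward_sim_cpp(state$counts, params$copies_per_deme,
                              params$mutation_rate, params$migration_rate,
                              params$n_generations)
    state <- new_allele_count_state(counts, params, params$n_generations)
  } else {
    for (g in seq_len(params$n_generations)) {
      state <- step_generation(state, params)
    }
  }
  class(state) <- c("ploidy_sim", class(state))
  state
}

#' @export
print.ploidy_sim <- function(x, ...) {
  fst <- tryCatch(suppressWarnings(multilocus_fst(x)), error = function(e) NA)
  cat(sprintf("Mixed-ploidy forward simulation after %d generations\n",
              x$generation))
  cat(sprintf("  %d demes x %d loci, %d genome copies per deme\n",
              x$params$n_demes, x$params$n_loci, x$params$copies_per_deme))
  cat(sprintf("  u = %g, m = %g, multilocus Fst = %s\n",
              x$params$mutation_rate, x$params$migration_rate,
              ifelse(is.na(fst), "undefined (all loci monomorphic)",
                     format(round(fst, 4)))))
  invisible(x)
}

#' @export
plot.ploidy_sim <- function(x, ...) {
  p <- x$counts / x$params$copies_per_deme
  graphics::plot(p[1L, ], p[2L, ], xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "allele-A frequency, deme 1",
                 ylab = "allele-A frequency, deme 2",
                 main = sprintf("m = %g, u = %g", x$params$migration_rate,
                                x$params$mutation_rate), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Frequency matrix of an allele-count state
#'
#' @param state an `allele_count_state` / `ploidy_sim`.
#' @return `n_demes x n_loci` matrix of allele-A frequencies.
#' @export
allele_freqs <- function(state) {
  state$counts / state$params$copies_per_deme
}

#' Multilocus F_st between the two demes
#'
#' Computed from the true deme allele frequencies. Per locus, `H_S` is the
#' mean over demes of `2 p (1 - p)` and `H_T = 2 pbar (1 - pbar)` with
#' `pbar` the mean frequency; multilocus values pool loci as ratios of
#' sums, which is robust to nearly monomorphic loci (each locus
#' contributes in proportion to its total diversity) and lets loci
#' monomorphic in both demes contribute zero to both sums.
#'
#' Two variants are offered. `standardized = FALSE` gives Nei's raw
#' multilocus G_st, `sum(H_T - H_S) / sum(H_T)`. The default
#' (`standardized = TRUE`) is the standardized measure
#' `k (H_T - H_S) / ((k H_T - H_S) (1 - H_S))` with `k = 2` demes
#' (computed on the multilocus mean diversities), which corrects both for
#' the small number of demes and for the within-deme diversity bound on
#' raw G_st. With only two demes and the substantial marker diversity the
#' simulations maintain, raw G_st is compressed far below the familiar
#' F_st scale (its maximum is well under 1); the standardized measure is
#' the deme-number- and diversity-corrected value on the usual scale, and
#' it is the differentiation axis used throughout the benchmark's
#' scenarios.
#'
#' @param state an `allele_count_state` / `ploidy_sim`, or a 2-row numeric
#'   matrix of allele frequencies.
#' @param standardized use the small-`k`, diversity-corrected measure
#'   (default) rather than raw G_st.
#' @return multilocus F_st in `[0, 1]`; `NA` with a warning when every locus
#'   is monomorphic across both demes (F_st undefined).
#' @export
multilocus_fst <- function(state, standardized = TRUE) {
  p <- if (is.matrix(state)) state else allele_freqs(state)
  if (any(p < 0 | p > 1)) stop("frequencies must lie in [0, 1]")
  k <- nrow(p)
  hs <- colMeans(2 * p * (1 - p))
  pbar <- colMeans(p)
  ht <- 2 * pbar * (1 - pbar)
  if (sum(ht) == 0) {
    warning("all loci monomorphic across demes; F_st undefined")
    return(NA_real_)
  }
  if (!standardized) return(sum(ht - hs) / sum(ht))
  HS <- mean(hs)
  HT <- mean(ht)
  if (HS >= 1 || k * HT - HS <= 0) return(0)
  k * (HT - HS) / ((k * HT - HS) * (1 - HS))
}

#' Independent replicate simulations from one master seed
#'
#' Derives one RNG stream per replicate from `seed` and runs
#' [run_simulation()] for each, so replicate `i` is reproducible in
#' isolation.
#'
#' @param params a [sim_params()] (its own `seed` is ignored here).
#' @param n_replicates number of independent runs.
#' @param seed master seed.
#' @return list of `ploidy_sim` objects.
#' @export
replicate_simulations <- function(params, n_replicates, seed) {
  seeds <- derive_seeds(seed, n_replicates)
  lapply(seq_len(n_replicates), function(i) {
    p <- params
    p$seed <- seeds[i]
    run_simulation(p)
  })
}

# Spawn child seeds from a master seed without disturbing correlations:
# a fixed-seed draw of distinct 31-bit integers.
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(n >= 0)
  if (n == 0L) return(integer(0))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer((as.numeric(seed) + 7919 * as.numeric(salt)) %%
                        .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}
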