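#' Specify a benchmark scenario
#'
#' A scenario is the cross of migration rates, locus counts and sample
#' sizes, each cell simulated `replicates` times, each replicate encoded
#' and clustered with every requested method x encoding combination and
#' scored with the beta-statistics.
#'
#' @param name scenario label carried into the results.
#' @param migration_rates vector of migration rates `m`.
#' @param n_loci_grid vector of locus counts.
#' @param n_individuals_grid vector of total sampled individuals (each
#'   value divisible by 4: split equally over 2 demes x 2 ploidies).
#' @param mutation_rate mutation rate `u`.
#' @param replicates independent simulations per grid cell.
#' @param methods subset of `c("kmeans", "bayes")`.
#' @param encodings subset of the five encodings (see [encode_genotypes()]).
#' @param n_generations forward-simulation length.
#' @param kmeans_starts random restarts for the k-means engine.
#' @param mcmc an [mcmc_settings()] for the Bayesian engine (its
#'   `replicates` field is the number of chains per dataset).
#' @param seed master seed; every cell derives its own stream.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(name = "custom",
                          migration_rates = default_migration_grid(),
                          n_loci_grid = 100L,
                          n_individuals_grid = 400L,
                          mutation_rate = 1e-4,
                          replicates = 10L,
                          methods = c("kmeans", "bayes"),
                          encodings = c("known_dosage", "unknown_dosage",
                                        "dominant"),
                          n_generations = 100000L,
                          kmeans_starts = 50L,
                          mcmc = mcmc_settings(burnin = 2000L,
                                               iterations = 10000L,
                                               replicates = 3L),
                          seed = 1L) {
  stopifnot(all(migration_rates > 0), all(n_loci_grid >= 1),
            all(n_individuals_grid >= 4), replicates >= 0)
  if (any(n_individuals_grid %% 4L != 0L))
    stop("n_individuals_grid values must be divisible by 4 ",
         "(2 demes x 2 ploidies, balanced)")
  methods <- match.arg(methods, c("kmeans", "bayes"), several.ok = TRUE)
  encodings <- match.arg(encodings, encodings(), several.ok = TRUE)
  structure(
    list(name = name, migration_rates = migration_rates,
         n_loci_grid = as.integer(n_loci_grid),
         n_individuals_grid = as.integer(n_individuals_grid),
         mutation_rate = mutation_rate, replicates = as.integer(replicates),
         methods = methods, encodings = encodings,
         n_generations = as.integer(n_generations),
         kmeans_starts = as.integer(kmeans_starts),
         mcmc = mcmc, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Default eight-rate migration grid
#'
#' Eight log-spaced migration rates spanning 0.001 to 0.1, covering
#' multilocus F_st from about 0 up to about 0.15 at equilibrium with the
#' default census sizes and mutation rate. The exact spacing of the grid
#' is a package choice; pass any custom vector to [scenario_spec()] to
#' override it.
#' @return numeric vector, decreasing in differentiation.
#' @export
default_migration_grid <- function() {
  round(exp(seq(log(0.1), log(0.001), length.out = 8L)), 6)
}

#' Built-in scenario presets
#'
#' * `default`: eight migration rates (0.001-0.1), 100 loci, 400
#'   individuals, `u = 1e-4`.
#' * `low_mutation`: as `default` with `u = 1e-5`.
#' * `tradeoff_weak` / `tradeoff_strong`: loci grid (10, 30, 100, 300,
#'   1000) x individuals grid (40, 120, 400) at `m = 0.01` (weak,
#'   F_st about 0.016) or `m = 0.001` (moderate, F_st about 0.12).
#' * `gbs`: genotyping-by-sequencing design, 40 individuals x 10,000
#'   loci, eight migration rates, no dominant encoding (such datasets do
#'   not occur in practice).
#'
#' @param scale factor in (0, 1] shrinking the desk-time cost: replicates
#'   and MCMC chain lengths are scaled down (with floors); forward
#'   simulations always run their full length.
#' @param seed master seed stored in each preset.
#' @return named list of `scenario_spec`s.
#' @export
builtin_specs <- function(scale = 1, seed = 1L) {
  stopifnot(scale > 0, scale <= 1)
  reps <- max(1L, as.integer(ceiling(10L * scale)))
  mc <- mcmc_settings(
    burnin = max(500L, as.integer(10000L * scale)),
    iterations = max(2000L, as.integer(100000L * scale)),
    replicates = max(1L, as.integer(ceiling(10L * scale)))
  )
  base <- scenario_spec(name = "default", replicates = reps, mcmc = mc,
                        seed = seed)
  low <- base; low$name <- "low_mutation"; low$mutation_rate <- 1e-5
  tw <- scenario_spec(name = "tradeoff_weak", migration_rates = 0.01,
                      n_loci_grid = c(10L, 30L, 100L, 300L, 1000L),
                      n_individuals_grid = c(40L, 120L, 400L),
                      replicates = reps, mcmc = mc, seed = seed)
  ts <- tw; ts$name <- "tradeoff_strong"; ts$migration_rates <- 0.001
  gbs <- scenario_spec(name = "gbs",
                       n_loci_grid = 10000L, n_individuals_grid = 40L,
                       encodings = c("known_dosage", "unknown_dosage"),
                       replicates = reps, mcmc = mc, seed = seed)
  list(default = base, low_mutation = low, tradeoff_weak = tw,
       tradeoff_strong = ts, gbs = gbs)
}

#' Run a scenario end to end
#'
#' For every migration rate x locus count x sample size x replicate:
#' simulate to equilibrium, sample genotypes, apply each requested
#' encoding, cluster with each requested method at `k = 2`, and score the
#' result with [evaluate_clustering()]. Fully reproducible from the
#' spec's master seed: every cell draws its simulation, sampling,
#' encoding and clustering streams from seeds derived once up front.
#'
#' @param spec a [scenario_spec()].
#' @param progress print one line per completed dataset.
#' @return a `scenario_results` data frame with one row per (cell,
#'   replicate, method, encoding): columns `scenario`, `m`, `n_loci`,
#'   `n_individuals`, `replicate`, `fst` (realized multilocus F_st of the
#'   replicate), `method`, `encoding`, `beta_pop`, `beta_ploidy`,
#'   `fit_score`.
#' @export
run_scenario <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  cells <- expand.grid(m = spec$migration_rates, n_loci = spec$n_loci_grid,
                       n_ind = spec$n_individuals_grid,
                       replicate = seq_len(spec$replicates),
                       KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  if (nrow(cells) > 0) {
    seeds <- matrix(derive_seeds(spec$seed, 4L * nrow(cells), salt = 3L),
                    ncol = 4L)
    for (ci in seq_len(nrow(cells))) {
      cell <- cells[ci, ]
      params <- sim_params(
        n_loci = cell$n_loci, migration_rate = cell$m,
        mutation_rate = spec$mutation_rate,
        n_generations = spec$n_generations, seed = seeds[ci, 1L]
      )
      sim <- run_simulation(params)
      fst <- suppressWarnings(multilocus_fst(sim))
      G <- sample_genotypes(sim, sample_design(cell$n_ind %/% 4L),
                            seed = seeds[ci, 2L])
      for (enc in spec$encodings) {
        D <- encode_genotypes(G, enc, seed = seeds[ci, 3L])
        for (method in spec$methods) {
          fit <- if (method == "kmeans") {
            km_cluster(D, k = 2L, n_starts = spec$kmeans_starts,
                       seed = seeds[ci, 4L])
          } else {
            st <- spec$mcmc
            st$seed <- seeds[ci, 4L]
            bayes_cluster(D, k = 2L, settings = st)
          }
          b <- evaluate_clustering(fit, G$deme, G$ploidy)
          rows[[length(rows) + 1L]] <- data.frame(
            scenario = spec$name, m = cell$m, n_loci = cell$n_loci,
            n_individuals = cell$n_ind, replicate = cell$replicate,
            fst = fst, method = method, encoding = enc,
            beta_pop = b$beta_pop, beta_ploidy = b$beta_ploidy,
            fit_score = fit$fit_score
          )
          if (progress)
            message(sprintf(
              "[%s] m=%g loci=%d n=%d rep=%d %s/%s: b_pop=%.2f b_plo=%.2f",
              spec$name, cell$m, cell$n_loci, cell$n_ind, cell$replicate,
              method, enc, b$beta_pop, b$beta_ploidy))
        }
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scenario = character(), m = numeric(), n_loci = integer(),
               n_individuals = integer(), replicate = integer(),
               fst = numeric(), method = character(), encoding = character(),
               beta_pop = numeric(), beta_ploidy = numeric(),
               fit_score = numeric())
  class(res) <- c("scenario_results", class(res))
  res
}

#' Write scenario results as TSV
#' @param res a `scenario_results` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Panel plot of correct versus biased clustering
#'
#' One panel per method x encoding, realized F_st on the x-axis, with
#' beta_pop in green (correct clustering by population) and beta_ploidy in
#' red (spurious clustering by ploidy).
#'
#' @param x a `scenario_results` data frame.
#' @param ... further arguments passed to `plot()`.
#' @export
plot.scenario_results <- function(x, ...) {
  combos <- unique(x[, c("method", "encoding")])
  old <- graphics::par(mfrow = c(length(unique(combos$method)),
                                 length(unique(combos$encoding))),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (r in seq_len(nrow(combos))) {
    sub <- x[x$method == combos$method[r] & x$encoding == combos$encoding[r], ]
    graphics::plot(sub$fst, sub$beta_pop, col = "darkgreen", pch = 16,
                   xlab = expression(F[st]), ylab = expression(beta),
                   ylim = c(0, 1),
                   main = paste(combos$method[r], combos$encoding[r]), ...)
    graphics::points(sub$fst, sub$beta_ploidy, col = "red", pch = 16)
  }
  invisible(x)
}
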