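tiny_spec <- function(...) {
  scenario_spec(name = "tiny", migration_rates = 0.05, n_loci_grid = 12L,
                n_individuals_grid = 16L, replicates = 2L,
                methods = "kmeans", encodings = c("known_dosage", "dominant"),
                n_generations = 300L, kmeans_starts = 10L, seed = 3L, ...)
}

test_that("run_scenario produces one scored row per dataset and is reproducible", {
  spec <- tiny_spec()
  res1 <- run_scenario(spec)
  res2 <- run_scenario(spec)
  expect_identical(res1, res2)
  expect_s3_class(res1, "scenario_results")
  expect_equal(nrow(res1), 2L * 2L)  # 2 replicates x 2 encodings
  expect_true(all(res1$beta_pop >= 0 & res1$beta_pop <= 1))
  expect_true(all(res1$beta_ploidy >= 0 & res1$beta_ploidy <= 1))
  expect_true(all(res1$beta_pop + res1$beta_ploidy <= 1 + 1e-12))
  expect_setequal(unique(res1$encoding), c("known_dosage", "dominant"))

  # a different master seed changes the draws
  spec2 <- tiny_spec(); spec2$seed <- 4L
  expect_false(identical(run_scenario(spec2)$fst, res1$fst))
})

test_that("zero replicates give an empty, well-formed table", {
  spec <- tiny_spec()
  spec$replicates <- 0L
  res <- run_scenario(spec)
  expect_equal(nrow(res), 0L)
  expect_true(all(c("scenario", "m", "fst", "method", "encoding",
                    "beta_pop", "beta_ploidy") %in% names(res)))
})

test_that("spec validation rejects malformed designs", {
  expect_error(scenario_spec(n_individuals_grid = 30L), "divisible by 4")
  expect_error(scenario_spec(methods = "dapc"))
  expect_error(scenario_spec(encodings = "haploid"))
  expect_error(scenario_spec(migration_rates = c(0.1, 0)))
})

test_that("presets carry the published designs", {
  specs <- builtin_specs()
  expect_named(specs, c("default", "low_mutation", "tradeoff_weak",
                        "tradeoff_strong", "gbs"))
  expect_length(specs$default$migration_rates, 8L)
  expect_equal(range(specs$default$migration_rates), c(0.001, 0.1))
  expect_equal(specs$default$n_loci_grid, 100L)
  expect_equal(specs$default$n_individuals_grid, 400L)
  expect_equal(specs$default$mutation_rate, 1e-4)
  expect_equal(specs$default$replicates, 10L)
  expect_equal(specs$low_mutation$mutation_rate, 1e-5)
  expect_equal(specs$tradeoff_weak$n_loci_grid, c(10L, 30L, 100L, 300L, 1000L))
  expect_equal(specs$tradeoff_weak$n_individuals_grid, c(40L, 120L, 400L))
  expect_equal(specs$tradeoff_weak$migration_rates, 0.01)
  expect_equal(specs$tradeoff_strong$migration_rates, 0.001)
  expect_equal(specs$gbs$n_loci_grid, 10000L)
  expect_equal(specs$gbs$n_individuals_grid, 40L)
  expect_false("dominant" %in% specs$gbs$encodings)

  small <- builtin_specs(scale = 0.1)
  expect_lt(small$default$replicates, specs$default$replicates)
  expect_lt(small$default$mcmc$iterations, specs$default$mcmc$iterations)
})

test_that("power grows with the number of loci for known-dosage data", {
  spec <- scenario_spec(name = "loci-power", migration_rates = 0.001,
                        n_loci_grid = c(10L, 100L), n_individuals_grid = 40L,
                        replicates = 3L, methods = "kmeans",
                        encodings = "known_dosage",
                        n_generations = 20000L, kmeans_starts = 20L,
                        seed = 11L)
  res <- run_scenario(spec)
  m10 <- mean(res$beta_pop[res$n_loci == 10L])
  m100 <- mean(res$beta_pop[res$n_loci == 100L])
  expect_gte(m100, m10)
})

test_that("a lower mutation rate reduces k-means ploidy bias on dominant data", {
  base <- scenario_spec(name = "u-default", migration_rates = 0.1,
                        n_loci_grid = 100L, n_individuals_grid = 80L,
                        replicates = 3L, methods = "kmeans",
                        encodings = "dominant", n_generations = 20000L,
                        kmeans_starts = 20L, seed = 21L)
  low <- base
  low$name <- "u-low"
  low$mutation_rate <- 1e-5
  bias_base <- mean(run_scenario(base)$beta_ploidy)
  bias_low <- mean(run_scenario(low)$beta_ploidy)
  expect_lt(bias_low, bias_base)
})
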