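test_that("mutation expectation is reversible and symmetric", {
  expect_equal(expected_freq_after_mutation(1.0, 1e-4), 0.9999)
  p <- c(0, 0.2, 0.5, 0.9, 1)
  expect_equal(expected_freq_after_mutation(p, 0), p)
  expect_equal(expected_freq_after_mutation(0.5, 0.3), 0.5)
  # result confined to [u, 1 - u]
  u <- 0.01
  out <- expected_freq_after_mutation(seq(0, 1, 0.1), u)
  expect_true(all(out >= u & out <= 1 - u))
  expect_error(expected_freq_after_mutation(1.2, 1e-4), "frequency")
  expect_error(expected_freq_after_mutation(0.5, 0.9), "mutation rate")
})

test_that("migration expectation mixes the two demes linearly", {
  expect_equal(expected_freq_after_migration(1, 1, 0.3), 1)
  expect_equal(expected_freq_after_migration(1, 0, 0.1), 0.9)
  expect_equal(expected_freq_after_migration(0.42, 0.87, 0), 0.42)
  expect_error(expected_freq_after_migration(0.5, 0.5, 0.7), "migration")
})

test_that("one generation is a binomial resampling of the copy pool", {
  # absorbing boundaries without mutation or migration
  params <- sim_params(n_loci = 4L, migration_rate = 0, mutation_rate = 0,
                       n_generations = 0L)
  st <- state_at_freqs(c(0, 1, 0, 1))
  st$params <- params
  st2 <- step_generation(st, params)
  expect_identical(st2$counts, st$counts)
  expect_identical(st2$generation, 1L)

  # moments at p = 0.5: mean 0.5, variance p(1-p)/copies
  set.seed(99)
  L <- 3000L
  params <- sim_params(n_loci = L, migration_rate = 0, mutation_rate = 0,
                       n_generations = 0L)
  st <- ploidyclust:::initial_state(params)
  draws <- as.vector(step_generation(st, params)$counts) / params$copies_per_deme
  expect_equal(mean(draws), 0.5, tolerance = 0.002)
  expect_equal(stats::var(draws), 0.25 / params$copies_per_deme,
               tolerance = 0.05)

  # at fixation with u = 1e-4 the binomial success probability is 0.9999
  params <- sim_params(n_loci = L, migration_rate = 0, mutation_rate = 1e-4,
                       n_generations = 0L)
  st <- ploidyclust:::initial_state(params)
  st$counts[] <- params$copies_per_deme
  draws <- as.vector(step_generation(st, params)$counts) / params$copies_per_deme
  expect_equal(mean(draws), 0.9999, tolerance = 3e-5)
})

test_that("run_simulation is reproducible and both engines agree exactly", {
  p <- sim_params(n_loci = 25L, migration_rate = 0.02, n_generations = 1500L,
                  seed = 7L)
  a <- run_simulation(p, engine = "r")
  b <- run_simulation(p, engine = "cpp")
  c2 <- run_simulation(p, engine = "cpp")
  expect_identical(a$counts, b$counts)
  expect_identical(b$counts, c2$counts)
  expect_identical(b$generation, 1500L)
})

test_that("zero generations returns the initial state; pure drift fixes loci", {
  p0 <- sim_params(n_loci = 10L, migration_rate = 0.01, n_generations = 0L,
                   seed = 1L)
  st <- run_simulation(p0)
  expect_true(all(st$counts == p0$copies_per_deme / 2L))

  pd <- sim_params(n_loci = 10L, migration_rate = 0, mutation_rate = 0,
                   n_diploids_per_deme = 3L, n_tetraploids_per_deme = 2L,
                   n_generations = 3000L, seed = 2L)
  st <- run_simulation(pd)
  expect_true(all(st$counts == 0L | st$counts == pd$copies_per_deme))
})

test_that("counts stay within the copy-pool bounds along a trajectory", {
  p <- sim_params(n_loci = 40L, migration_rate = 0.05, n_generations = 0L)
  st <- ploidyclust:::initial_state(p)
  set.seed(5)
  for (g in 1:50) {
    st <- step_generation(st, p)
    expect_true(all(st$counts >= 0L & st$counts <= p$copies_per_deme))
  }
})

test_that("multilocus F_st matches hand-computed cases", {
  # identical demes: no differentiation under either variant
  p_eq <- rbind(c(0.3, 0.7, 0.5), c(0.3, 0.7, 0.5))
  expect_equal(multilocus_fst(p_eq), 0)
  expect_equal(multilocus_fst(p_eq, standardized = FALSE), 0)
  # fixed difference at the only locus: complete differentiation
  p_fix <- rbind(1, 0)
  expect_equal(multilocus_fst(p_fix), 1)
  expect_equal(multilocus_fst(p_fix, standardized = FALSE), 1)
  # raw Nei G_st arithmetic: H_S = 0.32, H_T = 0.5
  expect_equal(multilocus_fst(rbind(0.2, 0.8), standardized = FALSE), 0.36)
  # undefined when nothing is polymorphic anywhere
  expect_warning(v <- multilocus_fst(rbind(c(1, 0), c(1, 0))), "monomorphic")
  expect_true(is.na(v))
})

test_that("equilibrium F_st decreases with migration and vanishes at m = 0.1", {
  # desk-scale version of the grid property: 3 rates, 3 replicates each
  rates <- c(0.1, 0.01, 0.001)
  means <- sapply(rates, function(m) {
    p <- sim_params(n_loci = 60L, migration_rate = m,
                    n_generations = 20000L)
    mean(sapply(replicate_simulations(p, 3L, seed = 17L), multilocus_fst))
  })
  expect_true(all(diff(means) > 0))  # fst grows as m falls
  expect_lt(means[1], 0.01)
})
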