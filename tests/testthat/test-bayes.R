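test_that("phenotype-legal dosage sets match the marker definitions", {
  expect_identical(phenotype_legal_dosages(AMBIGUOUS, 4L, "unknown_dosage"),
                   1:3)
  expect_identical(phenotype_legal_dosages(1, 2L, "dominant"), 1:2)
  expect_identical(phenotype_legal_dosages(1, 4L, "dominant"), 1:4)
  expect_identical(phenotype_legal_dosages(0, 4L, "dominant"), 0L)
  expect_identical(phenotype_legal_dosages(3, 4L, "known_dosage"), 3L)
  expect_identical(phenotype_legal_dosages(2, 2L, "unknown_dosage"), 2L)
  expect_error(phenotype_legal_dosages(5, 4L, "known_dosage"))
  expect_error(phenotype_legal_dosages(NA, 4L, "dominant"), "missing")
})

test_that("dosage full conditional matches brute-force enumeration", {
  # one tetraploid, one ambiguous locus, cluster frequency held at 0.7:
  # posterior over d in {1,2,3} is C(4,d) .7^d .3^(4-d), renormalized
  w <- choose(4, 1:3) * 0.7^(1:3) * 0.3^(4 - (1:3))
  expected_mean <- sum((1:3) * w) / sum(w)

  obs <- matrix(AMBIGUOUS, 1, 1)
  D <- ploidyclust:::new_encoded_dataset(obs, 4L, 1L, "unknown_dosage")
  fit <- bayes_cluster(D, k = 1L,
                       mcmc_settings(burnin = 200L, iterations = 20000L,
                                     replicates = 1L, seed = 8L),
                       fix_P = matrix(0.7, 1, 1))
  expect_equal(fit$mean_dosage[1, 1], expected_mean, tolerance = 0.02)

  # dominant presence on a diploid at p = 0.3: d in {1,2}, weights (.42, .09)
  wd <- c(2 * 0.3 * 0.7, 0.3^2)
  obs2 <- matrix(1L, 1, 1)
  D2 <- ploidyclust:::new_encoded_dataset(obs2, 2L, 1L, "dominant")
  fit2 <- bayes_cluster(D2, k = 1L,
                        mcmc_settings(burnin = 200L, iterations = 20000L,
                                      replicates = 1L, seed = 9L),
                        fix_P = matrix(0.3, 1, 1))
  expect_equal(fit2$mean_dosage[1, 1], sum((1:2) * wd) / sum(wd),
               tolerance = 0.02)
})

test_that("conjugate updates have the exact posterior moments", {
  # allele-frequency update: all n copies A gives Beta(n+1, 1), mean (n+1)/(n+2)
  state <- list(P = matrix(0.5, 1, 1), fix_P = FALSE,
                nA = matrix(8, 1, 1), nB = matrix(0, 1, 1))
  set.seed(12)
  draws <- replicate(20000, ploidyclust:::gibbs_update_P(state)$P[1, 1])
  expect_equal(mean(draws), 9 / 10, tolerance = 0.005)

  # symmetric counts: mean 0.5
  state$nA[] <- 5; state$nB[] <- 5
  draws <- replicate(5000, ploidyclust:::gibbs_update_P(state)$P[1, 1])
  expect_equal(mean(draws), 0.5, tolerance = 0.01)

  # admixture update: Dirichlet(alpha + counts) posterior mean
  st <- list(N = 1L, k = 2L, alpha = 1, mcnt = matrix(c(30, 10), 1, 2))
  set.seed(13)
  qs <- replicate(20000, ploidyclust:::gibbs_update_Q(st)$Q[1, 1])
  expect_equal(mean(qs), 31 / 42, tolerance = 0.005)
})

test_that("the alpha chain targets its conditional posterior", {
  # fixed Q; long Metropolis run vs the gridded density of the conditional
  set.seed(21)
  g <- matrix(stats::rgamma(40, 2), 20, 2)
  Q <- g / rowSums(g)
  st <- list(Q = Q, alpha = 1)
  trace <- numeric(30000)
  for (i in seq_along(trace)) {
    st <- ploidyclust:::gibbs_update_alpha(st, prop_sd = 0.3, alpha_max = 10)
    trace[i] <- st$alpha
  }
  grid <- seq(0.005, 10, by = 0.005)
  dens <- vapply(grid, function(a)
    exp(ploidyclust:::dirichlet_symm_logdens(Q, a) -
          ploidyclust:::dirichlet_symm_logdens(Q, 1)), numeric(1))
  dens <- dens / sum(dens)
  expect_equal(mean(trace[-(1:2000)]), sum(grid * dens), tolerance = 0.1)
})

test_that("compiled and pure-R samplers agree on a small instance", {
  G <- make_structured_genotypes(n_per_group = 3, n_loci = 12,
                                 p1 = 0.05, p2 = 0.95, seed = 6)
  D <- encode_unknown_dosage(G)
  st <- mcmc_settings(burnin = 300L, iterations = 1500L, replicates = 2L,
                      seed = 77L)
  fc <- bayes_cluster(D, 2, st, engine = "cpp")
  fr <- bayes_cluster(D, 2, st, engine = "r")
  bc <- beta_statistic(fc$membership[, 1], G$deme)
  br <- beta_statistic(fr$membership[, 1], G$deme)
  expect_equal(bc, br, tolerance = 0.05)
  expect_equal(fc$fit_score, fr$fit_score, tolerance = 0.05 * abs(fc$fit_score))
})

test_that("strong structure is recovered and no-signal data stays symmetric", {
  G <- make_structured_genotypes(n_per_group = 5, n_loci = 20, seed = 3)
  fit <- bayes_cluster(encode_known_dosage(G), 2,
                       mcmc_settings(500L, 2000L, replicates = 2L, seed = 5L))
  expect_gt(beta_statistic(fit$membership[, 1], G$deme), 0.95)
  expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))

  # identical rows: posterior mean membership near (0.5, 0.5) by symmetry
  dosage <- matrix(1L, 14, 6)
  Gi <- toy_genotypes(dosage, rep(2L, 14), rep(1:2, each = 7))
  fi <- bayes_cluster(encode_known_dosage(Gi), 2,
                      mcmc_settings(500L, 4000L, replicates = 1L, seed = 10L))
  expect_true(all(abs(fi$membership[, 1] - 0.5) < 0.2))
})

test_that("missing genotypes are tolerated and skipped", {
  G <- make_structured_genotypes(n_per_group = 3, n_loci = 10, seed = 15)
  v <- G$dosage
  v[1, 1:3] <- NA
  D <- ploidyclust:::new_encoded_dataset(v, G$ploidy, G$deme, "known_dosage")
  fit <- bayes_cluster(D, 2, mcmc_settings(200L, 800L, replicates = 1L,
                                           seed = 2L))
  expect_true(all(is.finite(fit$membership)))
  expect_gt(beta_statistic(fit$membership[, 1], G$deme), 0.8)
})

test_that("the best replicate is chosen by fit score with index tie-break", {
  mk <- function(score) ploidyclust:::new_cluster_fit(
    matrix(0.5, 2, 2), score, "bayes", 2L, extra = list(tag = score))
  expect_equal(best_of_replicates(list(mk(-100)))$fit_score, -100)
  expect_equal(best_of_replicates(list(mk(-100), mk(-90), mk(-95)))$fit_score,
               -90)
  tie <- best_of_replicates(list(mk(-50), mk(-50)))
  expect_equal(tie$tag, -50)
  expect_identical(which.max(c(-50, -50)), 1L)
})

test_that("bayes runs are deterministic given the seed", {
  G <- make_structured_genotypes(n_per_group = 3, n_loci = 8, seed = 30)
  D <- encode_dominant(G)
  st <- mcmc_settings(100L, 400L, replicates = 2L, seed = 55L)
  f1 <- bayes_cluster(D, 2, st)
  f2 <- bayes_cluster(D, 2, st)
  expect_identical(f1$membership, f2$membership)
  expect_identical(f1$replicate_scores, f2$replicate_scores)
})
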