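#' The beta-statistic: group separation of cluster assignments
#'
#' For a clustering at `k = 2`, `beta` is the absolute difference between
#' the two groups' mean proportion of assignment to the first cluster.
#' Equivalently it is the absolute value of the slope of a least-squares
#' regression (one-way ANOVA) of the assignment proportions on the 0/1
#' group indicator — the two formulations are algebraically identical and
#' [evaluate_clustering()] verifies the identity on every call. The value
#' ranges from 0 (no group signal) to 1 (perfect separation) and is
#' invariant both to swapping the cluster labels (`q1 -> 1 - q1`) and to
#' swapping the group labels, so no label-alignment step is needed
#' anywhere in the pipeline.
#'
#' @param q1 per-individual proportion assigned to cluster 1 (0/1 for hard
#'   clusterings).
#' @param labels binary grouping (factor, logical or two-valued vector);
#'   both groups must be non-empty.
#' @return the beta value in `[0, 1]`.
#' @export
#' @examples
#' beta_statistic(c(1, 1, 0, 0), c("a", "a", "b", "b"))  # 1
beta_statistic <- function(q1, labels) {
  if (any(q1 < 0 | q1 > 1)) stop("q1 entries must lie in [0, 1]")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must define exactly two groups")
  n_by <- table(labels)
  if (any(n_by == 0L)) stop("both groups must be non-empty")
  means <- tapply(q1, labels, mean)
  abs(means[[1L]] - means[[2L]])
}

#' Score a clustering against population and ploidy labels
#'
#' Computes `beta_pop` (how strongly the clustering separates the two
#' demes: correct structure) and `beta_ploidy` (how strongly it separates
#' the cytotypes: spurious structure, since the simulations build in no
#' divergence between ploidy levels) from the first membership column of a
#' `cluster_fit`. For the balanced crossed design used here the two
#' statistics cannot sum to more than 1. As a numerical cross-check the
#' mean-difference value is compared against the least-squares slope of
#' the 0/1-coded regression on each call.
#'
#' @param result a `cluster_fit` (or a bare membership matrix).
#' @param deme per-individual deme labels.
#' @param ploidy per-individual ploidy labels.
#' @return a `beta_result` with fields `beta_pop`, `beta_ploidy`, `method`,
#'   `fit_score`.
#' @export
evaluate_clustering <- function(result, deme, ploidy) {
  membership <- if (inherits(result, "cluster_fit")) result$membership else result
  stopifnot(is.matrix(membership), nrow(membership) == length(deme),
            length(deme) == length(ploidy))
  q1 <- membership[, 1L]
  b_pop <- beta_statistic(q1, deme)
  b_plo <- beta_statistic(q1, ploidy)
  # ANOVA-slope formulation must agree with the mean-difference form
  for (lab in list(deme, ploidy)) {
    g <- as.numeric(as.factor(lab)) - 1
    slope <- abs(stats::coef(stats::lm(q1 ~ g))[[2L]])
    ref <- beta_statistic(q1, lab)
    if (abs(slope - ref) > 1e-8)
      stop("internal error: slope and mean-difference formulations disagree")
  }
  structure(
    list(beta_pop = unname(b_pop), beta_ploidy = unname(b_plo),
         method = if (inherits(result, "cluster_fit")) result$method else NA,
         fit_score = if (inherits(result, "cluster_fit")) result$fit_score else NA),
    class = "beta_result"
  )
}

#' @export
print.beta_result <- function(x, ...) {
  cat(sprintf("beta_pop = %.3f (correct clustering by population)\n",
              x$beta_pop))
  cat(sprintf("beta_ploidy = %.3f (spurious clustering by ploidy)\n",
              x$beta_ploidy))
  invisible(x)
}
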