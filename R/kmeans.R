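#' Matrix of within-individual allele frequencies
#'
#' Converts an encoded dataset to the real-valued matrix the k-means engine
#' clusters on: each entry is the frequency of allele A within the
#' individual's own genotype. Diploid entries therefore take values in
#' {0, 0.5, 1} and tetraploid known-dosage entries in
#' {0, 0.25, 0.5, 0.75, 1}. Dominant entries are the presence bit itself.
#' An [AMBIGUOUS] tetraploid entry (phenotype AB, dosage unknown) is coded
#' 0.5, the midpoint of the dosages {1,2,3}/4 it is compatible with — the
#' natural expectation under a uniform dosage guess, and the coding under
#' which the documented ploidy bias of naive clustering arises.
#'
#' @param D an `encoded_dataset`.
#' @return numeric matrix, individuals x loci, entries in `[0, 1]`, with
#'   attributes `ploidy`, `deme` and `encoding` carried through.
#' @export
to_allele_freq_matrix <- function(D) {
  stopifnot(inherits(D, "encoded_dataset"))
  v <- D$values
  x <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  if (D$encoding == "dominant") {
    x[] <- as.numeric(v)
  } else {
    pl <- if (startsWith(D$encoding, "diploidized")) rep(2L, nrow(v)) else D$ploidy
    x[] <- v / pl
    x[v == AMBIGUOUS] <- 0.5
  }
  attr(x, "ploidy") <- D$ploidy
  attr(x, "deme") <- D$deme
  attr(x, "encoding") <- D$encoding
  x
}

new_cluster_fit <- function(membership, fit_score, method, k, extra = list()) {
  stopifnot(is.matrix(membership), ncol(membership) == k,
            all(abs(rowSums(membership) - 1) < 1e-8))
  structure(
    c(list(membership = membership, fit_score = fit_score,
           method = method, k = as.integer(k)), extra),
    class = "cluster_fit"
  )
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf("Cluster fit (%s, k = %d): %d individuals\n",
              x$method, x$k, nrow(x$membership)))
  score_name <- if (x$method == "kmeans") "within-cluster SS" else
    "mean log-likelihood"
  cat(sprintf("  fit score (%s): %s\n", score_name,
              format(signif(x$fit_score, 6))))
  cat("  mean membership in cluster 1:",
      format(round(mean(x$membership[, 1L]), 3)), "\n")
  invisible(x)
}

#' @export
summary.cluster_fit <- function(object, ...) {
  print(object)
  q1 <- object$membership[, 1L]
  cat("  q1 quartiles:", paste(format(round(stats::quantile(q1), 3)),
                               collapse = " "), "\n")
  invisible(object)
}

#' k-means clustering of individuals on allele frequencies
#'
#' Lloyd's algorithm minimising the total within-cluster sum of squares,
#' restarted from `n_starts` random initialisations (centroids drawn from
#' distinct data rows) and keeping the best solution. If a cluster empties
#' during an iteration its centroid is re-seeded to the point currently
#' farthest from its own centroid. This mirrors running a stand-alone
#' k-means on the within-individual allele-frequency matrix, without any
#' preceding PCA or discriminant step and without column scaling.
#'
#' @param x numeric matrix (individuals x loci), typically from
#'   [to_allele_freq_matrix()], or an `encoded_dataset` (converted
#'   automatically).
#' @param k number of clusters (2 throughout this benchmark).
#' @param n_starts random restarts.
#' @param max_iter iteration cap per start.
#' @param seed optional seed.
#' @return a `cluster_fit`: one-hot `membership` matrix (rows on the unit
#'   simplex), `fit_score` = achieved total within-cluster sum of squares,
#'   plus the integer `assignment` vector.
#' @export
#' @examples
#' x <- rbind(matrix(0, 5, 3), matrix(1, 5, 3))
#' km_cluster(x, k = 2, n_starts = 5, seed = 1)
km_cluster <- function(x, k = 2L, n_starts = 50L, max_iter = 300L,
                       seed = NULL) {
  if (inherits(x, "encoded_dataset")) x <- to_allele_freq_matrix(x)
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of individuals")
  ux <- unique(x)
  if (nrow(ux) < k) stop("fewer than k distinct rows")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (s in seq_len(n_starts)) {
    centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    assign_old <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      d2 <- dist2_to_centers(x, centers)
      assignment <- max.col(-d2, ties.method = "first")
      for (j in seq_len(k)) {
        idx <- which(assignment == j)
        if (length(idx) == 0L) {
          # re-seed empty cluster at the worst-fitted point
          far <- which.max(d2[cbind(seq_len(n), assignment)])
          assignment[far] <- j
          idx <- far
        }
        centers[j, ] <- colMeans(x[idx, , drop = FALSE])
      }
      if (identical(assignment, assign_old)) break
      assign_old <- assignment
    }
    ss <- sum((x - centers[assignment, , drop = FALSE])^2)
    if (is.null(best) || ss < best$ss - 1e-12) {
      best <- list(assignment = assignment, centers = centers, ss = ss)
    }
  }
  membership <- matrix(0, n, k)
  membership[cbind(seq_len(n), best$assignment)] <- 1
  new_cluster_fit(membership, best$ss, "kmeans", k,
                  extra = list(assignment = best$assignment,
                               centers = best$centers))
}

dist2_to_centers <- function(x, centers) {
  # squared Euclidean distances, n x k
  xs <- rowSums(x^2)
  cs <- rowSums(centers^2)
  outer(xs, cs, "+") - 2 * x %*% t(centers)
}
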