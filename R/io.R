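#' Write a simulation state as TSV with a JSON parameter sidecar
#'
#' One row per deme x locus with columns `deme`, `locus`, `count_A`,
#' `copies`, `frequency`; the simulation parameters (including the seed)
#' go to `<path>.json`.
#'
#' @param sim a `ploidy_sim`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sim_tsv <- function(sim, path) {
  p <- sim$params
  df <- data.frame(
    deme = rep(seq_len(p$n_demes), each = p$n_loci),
    locus = rep(seq_len(p$n_loci), times = p$n_demes),
    count_A = as.vector(t(sim$counts)),
    copies = p$copies_per_deme,
    frequency = as.vector(t(sim$counts)) / p$copies_per_deme
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- p[c("n_demes", "n_diploids_per_deme", "n_tetraploids_per_deme",
              "copies_per_deme", "n_loci", "mutation_rate",
              "migration_rate", "n_generations", "initial_freq", "seed")]
  side$generation <- sim$generation
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a simulation state written by [write_sim_tsv()]
#'
#' @param path the TSV path (the `<path>.json` sidecar must sit alongside).
#' @return a `ploidy_sim`.
#' @export
read_sim_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- sim_params(
    n_loci = side$n_loci, migration_rate = side$migration_rate,
    mutation_rate = side$mutation_rate,
    n_diploids_per_deme = side$n_diploids_per_deme,
    n_tetraploids_per_deme = side$n_tetraploids_per_deme,
    n_generations = side$n_generations, initial_freq = side$initial_freq,
    seed = side$seed
  )
  counts <- matrix(NA_integer_, params$n_demes, params$n_loci)
  counts[cbind(df$deme, df$locus)] <- df$count_A
  st <- new_allele_count_state(counts, params, side$generation)
  class(st) <- c("ploidy_sim", class(st))
  st
}

#' Write an encoded dataset in the mixed-ploidy Structure-style format
#'
#' One line per allele copy: every individual occupies `max(ploidy)` rows
#' (4 when tetraploids are present), columns are the individual label, the
#' deme label, then one column per locus. Alleles are coded `1` (A) and
#' `2` (B); diploids fill their surplus rows with the missing-data code
#' (default -9). An unknown-dosage tetraploid heterozygote is written as
#' one `1`, one `2` and two copies of the ambiguity fill code (default
#' -2), which downstream readers must treat as "dosage unknown", not
#' missing. Dominant data are written as presence/absence with the correct
#' per-individual ploidy: band presence as one `1` plus `ploidy - 1`
#' ambiguity codes (at least one dominant copy, the rest unknown), band
#' absence as `0` on all `ploidy` rows.
#'
#' With `style = "instruct"` the ambiguity code is replaced by the missing
#' code (the recoding historically used to feed such data to programs
#' without an ambiguity concept); the dataset itself is unchanged.
#'
#' Setting `haploid_dominant = TRUE` collapses dominant data to one 0/1
#' row per individual regardless of ploidy. That coding is known to induce
#' severe spurious clustering by ploidy and exists only to reproduce the
#' failure mode; a warning is always emitted.
#'
#' @param D an `encoded_dataset` (`known_dosage`, `unknown_dosage` or
#'   `dominant`).
#' @param path output path.
#' @param missing_code,ambiguity_code integer fill codes.
#' @param style `"structure"` or `"instruct"`.
#' @param haploid_dominant emit the biased haploid coding for dominant
#'   data (discouraged; warns).
#' @return `path`, invisibly.
#' @export
write_structure_file <- function(D, path, missing_code = -9L,
                                 ambiguity_code = -2L,
                                 style = c("structure", "instruct"),
                                 haploid_dominant = FALSE) {
  style <- match.arg(style)
  stopifnot(inherits(D, "encoded_dataset"))
  if (!D$encoding %in% c("known_dosage", "unknown_dosage", "dominant"))
    stop("diploidized datasets use the PLINK writer, not the Structure writer")
  if (style == "instruct") ambiguity_code <- missing_code
  n <- nrow(D$values)
  max_pl <- max(D$ploidy)
  lines <- character(0)
  for (i in seq_len(n)) {
    pl <- D$ploidy[i]
    v <- D$values[i, ]
    if (D$encoding == "dominant" && haploid_dominant) {
      rows <- matrix(v, nrow = 1L)
    } else {
      rows <- matrix(missing_code, nrow = max_pl, ncol = length(v))
      for (j in seq_along(v)) {
        rows[seq_len(pl), j] <- copy_codes(v[j], pl, D$encoding,
                                           missing_code, ambiguity_code)
      }
    }
    lab <- sprintf("ind_%03d", i)
    for (r in seq_len(nrow(rows))) {
      lines <- c(lines, paste(c(lab, D$deme[i], rows[r, ]), collapse = "\t"))
    }
  }
  if (D$encoding == "dominant" && haploid_dominant)
    warning("haploid coding of dominant mixed-ploidy data induces strong ",
            "spurious clustering by ploidy; use only to study that bias")
  writeLines(lines, path)
  invisible(path)
}

# the per-locus column of allele-copy codes for one individual
copy_codes <- function(value, pl, encoding, missing_code, ambiguity_code) {
  if (is.na(value)) return(rep(missing_code, pl))
  if (encoding == "dominant") {
    if (value == 0L) return(rep(0L, pl))
    return(c(1L, rep(ambiguity_code, pl - 1L)))
  }
  if (encoding == "unknown_dosage" && value == AMBIGUOUS) {
    return(c(1L, 2L, rep(ambiguity_code, pl - 2L)))
  }
  c(rep(1L, value), rep(2L, pl - value))
}

#' Read a mixed-ploidy Structure-style file written by
#' [write_structure_file()]
#'
#' Ploidy is recovered per individual as the number of rows that are not
#' pure missing-data padding; values are decoded according to `encoding`.
#'
#' @param path input path.
#' @param encoding the encoding the file was written with.
#' @param missing_code,ambiguity_code the fill codes used at write time.
#' @return an `encoded_dataset`.
#' @export
read_structure_file <- function(path, encoding,
                                missing_code = -9L, ambiguity_code = -2L) {
  encoding <- match.arg(encoding,
                        c("known_dosage", "unknown_dosage", "dominant"))
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  labs <- unique(raw[[1L]])
  n <- length(labs)
  L <- ncol(raw) - 2L
  values <- matrix(NA_integer_, n, L,
                   dimnames = list(labs, sprintf("L%03d", seq_len(L))))
  ploidy <- integer(n)
  deme <- integer(n)
  for (i in seq_len(n)) {
    block <- as.matrix(raw[raw[[1L]] == labs[i], -(1:2), drop = FALSE])
    deme[i] <- raw[raw[[1L]] == labs[i], 2L][1L]
    pad <- apply(block, 1L, function(r) all(r == missing_code))
    ploidy[i] <- sum(!pad)
    block <- block[!pad, , drop = FALSE]
    for (j in seq_len(L)) {
      col <- block[, j]
      if (all(col == missing_code)) next
      if (encoding == "dominant") {
        values[i, j] <- as.integer(any(col == 1L))
      } else if (any(col == ambiguity_code)) {
        values[i, j] <- AMBIGUOUS
      } else {
        values[i, j] <- sum(col == 1L)
      }
    }
  }
  new_encoded_dataset(values, ploidy, deme, encoding)
}

#' Write a diploidized dataset as PLINK-style .ped/.map text files
#'
#' @param D an `encoded_dataset` whose rows are all diploid
#'   (`diploidized_known` or `diploidized_unknown`).
#' @param prefix output prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(D, prefix) {
  stopifnot(inherits(D, "encoded_dataset"))
  if (!startsWith(D$encoding, "diploidized"))
    stop("the PLINK writer takes diploidized datasets only")
  v <- D$values
  n <- nrow(v); L <- ncol(v)
  ped <- character(n)
  for (i in seq_len(n)) {
    al <- character(2L * L)
    for (j in seq_len(L)) {
      d <- v[i, j]
      g <- if (is.na(d)) c("0", "0") else
        c(rep("A", d), rep("B", 2L - d))
      al[c(2L * j - 1L, 2L * j)] <- g
    }
    ped[i] <- paste(c(sprintf("FAM%d", D$deme[i]), sprintf("ind_%03d", i),
                      0, 0, 0, -9, al), collapse = " ")
  }
  writeLines(ped, paste0(prefix, ".ped"))
  map <- sprintf("1 snp_%05d 0 %d", seq_len(L), seq_len(L) * 1000L)
  writeLines(map, paste0(prefix, ".map"))
  invisible(prefix)
}

#' Write / read an encoded dataset as a generic TSV genotype matrix
#'
#' Columns `id`, `deme`, `ploidy`, then one column per locus; a first
#' comment line carries the encoding. Ambiguous entries are stored as the
#' [AMBIGUOUS] sentinel and missing entries as `NA`.
#'
#' @param D an `encoded_dataset`.
#' @param path file path.
#' @return `path` (writer) or an `encoded_dataset` (reader).
#' @export
write_genotype_tsv <- function(D, path) {
  stopifnot(inherits(D, "encoded_dataset"))
  df <- data.frame(id = sprintf("ind_%03d", seq_len(nrow(D$values))),
                   deme = D$deme, ploidy = D$ploidy)
  df <- cbind(df, as.data.frame(D$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# encoding=%s", D$encoding), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @export
read_genotype_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  encoding <- sub("^# encoding=", "", first)
  encoding <- match.arg(encoding, encodings())
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(v) <- "integer"
  rownames(v) <- df$id
  new_encoded_dataset(v, df$ploidy, df$deme, encoding)
}

#' Write per-iteration MCMC diagnostics as TSV
#'
#' One row per stored sweep of the selected replicate chain with columns
#' `iteration`, `loglik`, `alpha`, so convergence can be inspected with
#' any plotting tool.
#'
#' @param fit a `cluster_fit` from [bayes_cluster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diagnostics_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "cluster_fit"))
  if (is.null(fit$loglik_trace))
    stop("no MCMC traces on this fit (k-means fits have none)")
  df <- data.frame(iteration = seq_along(fit$loglik_trace),
                   loglik = fit$loglik_trace,
                   alpha = fit$alpha_trace)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
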