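# Deterministic synthetic fixtures: codon-usage vectors, CDS FASTA with
# planted composition, and stochastic codon matrices from random reversible
# generators. Used by the test-suite and exposed through the CLI.

#' Synthetic codon usage from a Dirichlet draw
#'
#' Samples a codon-usage vector from a symmetric Dirichlet distribution over
#' the 61 sense codons. The default concentration `alpha = 2` gives a
#' realistic genome-like dispersion (codon frequencies spreading roughly an
#' order of magnitude around 1/61).
#'
#' @param alpha Dirichlet concentration (> 0).
#' @param seed optional integer seed.
#' @return a [codon_usage] vector.
#' @export
dirichlet_codon_usage <- function(alpha = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rgamma(61, shape = alpha)
  codon_usage(stats::setNames(g / sum(g), SENSE_CODONS))
}

#' Synthetic stochastic codon matrix from a random reversible generator
#'
#' Builds a random reversible generator on all 64 codons (symmetric
#' single-nucleotide exchangeabilities times Dirichlet stationary
#' frequencies), scales it to one substitution per codon per unit time, and
#' exponentiates at `t` — an empirical-channel-like stochastic matrix with a
#' known construction.
#'
#' @param t exponentiation time (default 1).
#' @param seed optional integer seed.
#' @return 64x64 row-stochastic matrix with codon dimnames.
#' @export
synthetic_codon_channel <- function(t = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- stats::rgamma(64, shape = 2)
  pi64 <- g / sum(g)
  ns <- .neighbour_structure(CODONS)
  ex <- matrix(0, 64, 64)
  ex[ns$neighbour] <- stats::rgamma(sum(ns$neighbour), shape = 1)
  ex <- (ex + t(ex)) / 2                      # symmetric exchangeabilities
  R <- ex * matrix(pi64, 64, 64, byrow = TRUE)
  diag(R) <- -rowSums(R)
  R <- R / -sum(pi64 * diag(R))
  dimnames(R) <- list(CODONS, CODONS)
  P <- as.matrix(Matrix::expm(R * t))
  dimnames(P) <- list(CODONS, CODONS)
  P
}

#' Synthetic CDS FASTA with planted codon composition
#'
#' Writes a multi-FASTA of coding sequences assembled from a planted codon
#' count vector (shuffled deterministically, split across records, each ended
#' with a stop codon), so [codon_usage_from_cds()] recovers the planted
#' frequencies exactly.
#'
#' @param counts named integer vector of sense-codon counts.
#' @param path output FASTA path.
#' @param n_records number of CDS records to split the codons across.
#' @param seed optional integer seed (controls the shuffle).
#' @return `path`, invisibly; attribute `usage` holds the planted
#'   [codon_usage].
#' @export
synthetic_cds_fasta <- function(counts, path, n_records = 3, seed = NULL) {
  counts <- counts[counts > 0]
  names(counts) <- .check_codons(names(counts))
  stopifnot(all(names(counts) %in% SENSE_CODONS))
  if (!is.null(seed)) set.seed(seed)
  codons <- sample(rep(names(counts), counts))
  splits <- cut(seq_along(codons), breaks = n_records, labels = FALSE)
  lines <- unlist(lapply(seq_len(n_records), function(k) {
    cds <- paste(c(codons[splits == k], sample(STOP_CODONS, 1)), collapse = "")
    c(paste0(">synthetic_cds_", k), cds)
  }))
  writeLines(lines, path)
  out <- invisible(path)
  attr(out, "usage") <- codon_usage(counts / sum(counts))
  out
}

#' Generate named fixture files
#'
#' Deterministic synthetic inputs for tests and examples. Kinds:
#' `"usage-uniform"` (uniform codon-usage TSV), `"usage-dirichlet"`
#' (Dirichlet-sampled usage TSV), `"cds-fasta"` (synthetic CDS FASTA with
#' known composition), `"empirical-matrix"` (synthetic stochastic codon
#' matrix TSV).
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed; the same seed yields byte-identical files.
#' @param dir output directory (created if needed).
#' @return path of the written file, invisibly.
#' @export
generate_fixtures <- function(kind, seed = 1L, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(kind, ".tsv"))
  switch(kind,
    "usage-uniform" = write_codon_usage(uniform_codon_usage(), path),
    "usage-dirichlet" = write_codon_usage(dirichlet_codon_usage(seed = seed), path),
    "cds-fasta" = {
      path <- file.path(dir, "cds-fasta.fasta")
      set.seed(seed)
      counts <- stats::setNames(sample(0:20, 61, replace = TRUE), SENSE_CODONS)
      counts["ATG"] <- max(counts["ATG"], 1L)
      synthetic_cds_fasta(counts, path, seed = seed)
    },
    "empirical-matrix" = write_codon_matrix(synthetic_codon_channel(seed = seed), path),
    stop("unknown fixture kind: ", kind))
  invisible(path)
}
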