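# Monte-Carlo verification of the analytic frame predictions: simulate codon
# sequences under the frame +1 channel and measure alternative-frame
# statistics empirically.

#' Sample a stationary codon sequence
#'
#' Draws `n` i.i.d. sense codons from the codon usage `pi^+1` (the codons are
#' transmitted independently over the evolutionary channel, i.e. a discrete
#' memoryless channel).
#'
#' @param n sequence length in codons (>= 1).
#' @param usage a [codon_usage] vector.
#' @param seed optional integer seed for reproducibility.
#' @return character vector of codons.
#' @export
sample_stationary_sequence <- function(n, usage, seed = NULL) {
  usage <- codon_usage(usage)
  if (!is.null(seed)) set.seed(seed)
  sample(names(usage), n, replace = TRUE, prob = as.numeric(usage))
}

#' Evolve a codon sequence through a transition matrix
#'
#' Replaces every codon independently by a draw from its row of `P` — the
#' discrete channel use. Equivalent in law to simulating the continuous-time
#' chain for the corresponding horizon.
#'
#' @param seq character vector of codons, all present among `rownames(P)`.
#' @param P row-stochastic transition matrix with codon dimnames.
#' @param seed optional integer seed.
#' @return character vector of evolved codons.
#' @export
evolve_sequence <- function(seq, P, seed = NULL) {
  if (is.null(rownames(P)) || is.null(colnames(P)))
    stop("'P' must carry codon dimnames")
  idx <- match(seq, rownames(P))
  if (anyNA(idx)) stop("sequence contains codons outside the state space of P")
  if (!is.null(seed)) set.seed(seed)
  out <- integer(length(seq))
  for (x in unique(idx)) {
    at <- which(idx == x)
    out[at] <- sample.int(ncol(P), length(at), replace = TRUE, prob = P[x, ])
  }
  colnames(P)[out]
}

#' Empirical codon frequencies in a reading frame
#'
#' Slides over consecutive codon pairs (overlapping 6-nucleotide windows),
#' extracts the frame sub-codon of each window and tabulates frequencies over
#' the 64-codon container.
#'
#' @param seq character vector of codons, length >= 2.
#' @param frame a reading-frame label.
#' @return named frequency vector over [CODONS], summing to one.
#' @export
empirical_frame_frequencies <- function(seq, frame) {
  .check_frame(frame)
  n <- length(seq)
  if (n < 2L) stop("sequence must contain at least 2 codons")
  windows <- paste0(seq[-n], seq[-1L])
  sub <- frame_subcodon(windows, frame)
  counts <- table(factor(sub, levels = CODONS))
  freqs <- as.numeric(counts) / sum(counts)
  stats::setNames(freqs, CODONS)
}

#' Empirical frame transition frequencies
#'
#' Pairs the frame sub-codons of matching windows in an ancestral and an
#' evolved sequence and tabulates conditional transition frequencies — the
#' empirical counterpart of `transition_matrix(Q^f, t)`.
#'
#' @param seq,evolved codon sequences of equal length.
#' @param frame a reading-frame label.
#' @param stride spacing between window start codons; the default 1 uses all
#'   overlapping windows, 2 gives disjoint (independent) windows.
#' @return list with `P` (row-normalised 64x64 matrix; rows with no
#'   observations are `NA`) and `counts` (per-row window counts).
#' @export
empirical_frame_transitions <- function(seq, evolved, frame, stride = 1L) {
  .check_frame(frame)
  stopifnot(length(seq) == length(evolved), length(seq) >= 2L, stride >= 1L)
  n <- length(seq)
  at <- seq.int(1L, n - 1L, by = stride)
  from <- frame_subcodon(paste0(seq[at], seq[at + 1L]), frame)
  to <- frame_subcodon(paste0(evolved[at], evolved[at + 1L]), frame)
  tab <- table(factor(from, levels = CODONS), factor(to, levels = CODONS))
  counts <- rowSums(tab)
  P <- sweep(unclass(tab), 1, counts, "/")
  P[counts == 0, ] <- NA_real_
  list(P = P, counts = counts)
}
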