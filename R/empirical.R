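# Robustness mode: project an externally supplied empirical codon transition
# matrix (e.g. an empirical codon substitution matrix estimated from
# alignments) into the alternative reading frames.

#' Empirical codon transition channel
#'
#' Validates a codon-labelled row-stochastic matrix (64x64, or 61x61 over the
#' sense codons). Stop rows may be dropped or kept.
#'
#' @param P square stochastic matrix with codon dimnames, or a TSV path
#'   (see [read_codon_matrix()]).
#' @param label free-text label for the matrix.
#' @param drop_stops drop stop rows/columns and renormalise (default `FALSE`).
#' @return object of class `empirical_channel` with elements `P`, `states`,
#'   `label`.
#' @export
empirical_channel <- function(P, label = "empirical", drop_stops = FALSE) {
  if (is.character(P) && length(P) == 1L) P <- read_codon_matrix(P)
  stopifnot(is.matrix(P))
  states <- .check_codons(rownames(P))
  if (!all(states %in% CODONS)) stop("unknown codon labels in matrix")
  if (drop_stops) {
    keep <- !states %in% STOP_CODONS
    P <- P[keep, keep, drop = FALSE]
    P <- P / rowSums(P)
    states <- states[keep]
  }
  if (any(P < 0)) stop("channel matrix has negative entries")
  bad <- abs(rowSums(P) - 1) > 1e-8
  if (any(bad))
    stop("channel rows do not sum to 1: ", paste(states[bad], collapse = ", "))
  structure(list(P = P, states = states, label = label),
            class = "empirical_channel")
}

#' @rdname empirical_channel
#' @export
load_codon_matrix <- function(path, label = basename(path), drop_stops = FALSE) {
  empirical_channel(read_codon_matrix(path), label = label,
                    drop_stops = drop_stops)
}

#' @export
print.empirical_channel <- function(x, ...) {
  cat(sprintf("Empirical codon channel '%s' over %d states\n",
              x$label, length(x$states)))
  invisible(x)
}

.mat_power <- function(M, k) {
  stopifnot(k >= 1, k == round(k))
  out <- M
  for (i in seq_len(k - 1)) out <- out %*% M
  out
}

#' Project an empirical codon channel into a reading frame
#'
#' Forms the di-codon product channel — both codons of a sense-codon pair
#' transition independently through `P^steps` (evolutionary time is realised
#' as integer matrix powers of the supplied channel) — and marginalises it
#' onto the frame sub-codon, weighting the flanks by the conditional
#' distribution of the pair given the sub-codon under `usage (x) usage`
#' (the same weighting rule as the rate-matrix projection).
#'
#' @param ch an [empirical_channel].
#' @param usage flank-weighting codon usage (a [codon_usage] vector); use the
#'   channel's own stationary vector by passing it explicitly.
#' @param frame a reading-frame label.
#' @param steps number of channel applications, >= 1.
#' @return list with `P` (row-stochastic matrix over the frame's supported
#'   states), `pi` (frame marginal of `usage`), `frame`, `steps`, and
#'   `dropped` zero-support states.
#' @export
project_transition_matrix <- function(ch, usage, frame, steps = 1L) {
  stopifnot(inherits(ch, "empirical_channel"))
  .check_frame(frame)
  usage <- codon_usage(usage)
  if (!all(SENSE_CODONS %in% ch$states))
    stop("channel must cover the 61 sense codons")
  M <- .mat_power(ch$P, steps)
  if (frame == "+1") {
    Ms <- M[SENSE_CODONS, SENSE_CODONS, drop = FALSE]
    Ms <- Ms / rowSums(Ms)
    return(list(P = Ms,
                pi = stats::setNames(as.numeric(usage), SENSE_CODONS),
                frame = frame, steps = steps, dropped = character(0)))
  }
  n1 <- length(SENSE_CODONS)
  K <- length(ch$states)
  Msense <- M[SENSE_CODONS, , drop = FALSE]
  i1 <- rep(seq_len(n1), each = n1)
  i2 <- rep(seq_len(n1), times = n1)
  windows <- paste0(SENSE_CODONS[i1], SENSE_CODONS[i2])
  sub_src <- match(frame_subcodon(windows, frame), CODONS)
  pi2 <- as.numeric(usage)[i1] * as.numeric(usage)[i2]
  pif64 <- .frame_marginal(pi2, sub_src)
  w <- ifelse(pif64[sub_src] > 0, pi2 / pif64[sub_src], 0)
  W <- Matrix::sparseMatrix(i = seq_along(w), j = sub_src, x = w,
                            dims = c(length(w), 64))
  # destination pairs range over the channel's full state set
  j1 <- rep(seq_len(K), each = K)
  j2 <- rep(seq_len(K), times = K)
  dest_windows <- paste0(ch$states[j1], ch$states[j2])
  sub_dst <- match(frame_subcodon(dest_windows, frame), CODONS)
  S <- Matrix::sparseMatrix(i = seq_along(sub_dst), j = sub_dst, x = 1,
                            dims = c(length(sub_dst), 64))
  D <- kronecker(Msense, Msense)                # 3721 x K^2 product channel
  Pf64 <- as.matrix(Matrix::crossprod(W, D %*% S))
  support <- pif64 > 0
  dropped <- CODONS[!support]
  Pf <- Pf64[support, support, drop = FALSE]
  Pf <- Pf / rowSums(Pf)
  dimnames(Pf) <- list(CODONS[support], CODONS[support])
  list(P = Pf, pi = stats::setNames(pif64[support], CODONS[support]),
       frame = frame, steps = steps, dropped = dropped)
}

#' Information measures from a projected empirical channel
#'
#' Aggregates a projected codon channel to amino acids (same pooling as
#' [aa_channel()]) and returns conditional entropy and mutual information.
#'
#' @param proj result of [project_transition_matrix()].
#' @return list with `conditional_entropy`, `mutual_information` (bits) and
#'   the `aa_channel`-style aggregate.
#' @export
empirical_info <- function(proj) {
  agg <- .aa_aggregate(proj$P, as.numeric(proj$pi), rownames(proj$P))
  ch <- structure(list(P = agg$P, alphabet = agg$alphabet,
                       dropped = agg$dropped, frame = proj$frame,
                       t = proj$steps),
                  class = "aa_channel")
  list(conditional_entropy = conditional_entropy(ch),
       mutual_information = mutual_information(ch),
       channel = ch)
}
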