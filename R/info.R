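# Amino-acid evolutionary channel and information measures: conditional
# entropy (genetic noise), mutual information (sequence similarity), and the
# half-information time per reading frame.

# Aggregate a codon-level stochastic matrix to amino acids. Stop rows/columns
# and zero-weight rows are removed before aggregation, rows renormalised, and
# codon rows pooled within each amino acid by their stationary weights
# w(x|a) = pi_x / sum_{x' in a} pi_x'.
.aa_aggregate <- function(P, weights, states) {
  aa <- translate_codon(states)
  keep <- aa != "*" & weights > 0
  dropped <- setdiff(setdiff(unique(aa), "*"), unique(aa[keep]))
  P <- P[keep, keep, drop = FALSE]
  P <- P / rowSums(P)
  aa <- aa[keep]
  w <- weights[keep]
  grp_tot <- tapply(w, aa, sum)
  wn <- w / as.numeric(grp_tot[aa])
  Pa <- rowsum(P * wn, aa)                      # rows pooled within amino acid
  Pab <- t(rowsum(t(Pa), aa))                   # columns summed within amino acid
  alphabet <- sort(rownames(Pa))
  Pab <- Pab[alphabet, alphabet, drop = FALSE]
  list(P = Pab, alphabet = alphabet, dropped = dropped)
}

#' Amino-acid evolutionary channel of a reading frame
#'
#' Exponentiates the frame generator to `P^f(t)`, removes stop codon rows and
#' columns, renormalises, and pools codons into amino acids using the
#' conditional stationary weights `pi^f_x / sum_{x' in a} pi^f_{x'}`. The
#' result is the stochastic matrix `P(b | a)`: the probability that amino acid
#' `a` read in frame f becomes `b` after time `t`. Amino acids without
#' stationary support in the frame are dropped and flagged (the alphabet
#' shrinks).
#'
#' @param fm a `frame_model`.
#' @param t evolutionary time, >= 0.
#' @return object of class `aa_channel`: stochastic matrix `P`, `alphabet`,
#'   `dropped` symbols, `frame`, `t`.
#' @export
aa_channel <- function(fm, t) {
  stopifnot(inherits(fm, "frame_model"))
  P <- transition_matrix(fm, t)
  agg <- .aa_aggregate(P, as.numeric(fm$pi), fm$states)
  structure(list(P = agg$P, alphabet = agg$alphabet, dropped = agg$dropped,
                 frame = fm$frame, t = t),
            class = "aa_channel")
}

#' @export
print.aa_channel <- function(x, ...) {
  cat(sprintf("Amino-acid channel: frame %s, t = %g, |alphabet| = %d\n",
              x$frame, x$t, length(x$alphabet)))
  if (length(x$dropped)) cat("  dropped symbols:", paste(x$dropped, collapse = " "), "\n")
  invisible(x)
}

.row_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.channel_matrix <- function(ch) {
  if (inherits(ch, "aa_channel")) ch$P
  else if (is.matrix(ch)) ch
  else stop("'ch' must be an aa_channel or a stochastic matrix")
}

#' Conditional entropy of a channel (bits)
#'
#' Uniformly weighted conditional entropy
#' `H(Y|X) = (1/|A|) sum_a H(Y | X = a)` with
#' `H(Y|X=a) = -sum_b P(b|a) log2 P(b|a)` (0 log 0 = 0). With the full
#' 20-letter alphabet it is bounded by `log2(20) ~ 4.32` bits; it measures the
#' genetic noise accumulated after time t.
#'
#' @param ch an [aa_channel] or a row-stochastic matrix.
#' @return entropy in bits.
#' @export
conditional_entropy <- function(ch) {
  P <- .channel_matrix(ch)
  mean(apply(P, 1, .row_entropy))
}

#' Mutual information of a channel (bits)
#'
#' `I(X;Y)` for `X` uniform over the channel alphabet:
#' `I = H(Y) - H(Y|X)` where `H(Y)` is the entropy of the output distribution
#' `colMeans(P)`. It measures the similarity between ancestral and descendant
#' sequence and equals `log2 |alphabet|` at t = 0.
#'
#' @param ch an [aa_channel] or a row-stochastic matrix.
#' @return mutual information in bits.
#' @export
mutual_information <- function(ch) {
  P <- .channel_matrix(ch)
  .row_entropy(colMeans(P)) - conditional_entropy(P)
}

#' Half-information time of a reading frame
#'
#' The evolutionary time at which the conditional entropy of the frame's
#' amino-acid channel reaches half of the maximal uncertainty, by default
#' `log2(20)/2 ~ 2.16` bits regardless of any alphabet reduction
#' (`reduced_alphabet = TRUE` uses `log2 |alphabet| / 2` instead). Found by
#' bisection on `interval` to absolute tolerance `tol`; the conditional
#' entropy is continuous and increasing in t on the bracket.
#'
#' @param fm a `frame_model`.
#' @param interval search bracket for t (default `c(0, 20)`).
#' @param tol absolute tolerance on t (default 1e-4).
#' @param reduced_alphabet use the realised alphabet size for the threshold.
#' @return the crossing time t.
#' @export
half_information_time <- function(fm, interval = c(0, 20), tol = 1e-4,
                                  reduced_alphabet = FALSE) {
  nsym <- if (reduced_alphabet) length(aa_channel(fm, 0)$alphabet) else 20L
  thr <- log2(nsym) / 2
  h <- function(t) conditional_entropy(aa_channel(fm, t)) - thr
  lo <- interval[1]; hi <- interval[2]
  flo <- h(lo); fhi <- h(hi)
  if (flo > 0 || fhi < 0)
    stop("half-information threshold not bracketed on [",
         lo, ", ", hi, "]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (h(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Entropy and mutual-information profile over time
#'
#' @param fm a `frame_model`.
#' @param times numeric vector of times.
#' @return `data.frame` with columns `t`, `conditional_entropy`,
#'   `mutual_information` (bits).
#' @export
info_profile <- function(fm, times = seq(0, 5, by = 0.1)) {
  rows <- lapply(times, function(t) {
    ch <- aa_channel(fm, t)
    data.frame(t = t, conditional_entropy = conditional_entropy(ch),
               mutual_information = mutual_information(ch))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
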