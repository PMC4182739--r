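# Goldman-Yang (M0) codon rate matrix: construction, scaling, exponentiation,
# stationary distribution.

# Pairwise single-nucleotide structure of a codon state set: which ordered
# pairs are single-nucleotide neighbours, whether the change is a transition
# (A<->G, C<->T), and whether it is synonymous under the standard code
# (the stop label "*" counts as a 21st symbol where present).
.neighbour_structure <- function(states) {
  n <- length(states)
  chars <- matrix(unlist(strsplit(states, "", fixed = TRUE)), ncol = 3, byrow = TRUE)
  diff_at <- array(FALSE, c(n, n, 3))
  trans_at <- array(FALSE, c(n, n, 3))
  purine <- c("A", "G")
  for (k in 1:3) {
    diff_at[, , k] <- outer(chars[, k], chars[, k], "!=")
    same_class <- outer(chars[, k] %in% purine, chars[, k] %in% purine, "==")
    trans_at[, , k] <- diff_at[, , k] & same_class
  }
  hamming <- diff_at[, , 1] + diff_at[, , 2] + diff_at[, , 3]
  neighbour <- hamming == 1L
  transition <- neighbour & (trans_at[, , 1] | trans_at[, , 2] | trans_at[, , 3])
  aa <- translate_codon(states)
  synonymous <- outer(aa, aa, "==")
  list(neighbour = neighbour, transition = transition, synonymous = synonymous,
       aa = aa)
}

# Unscaled M0-form generator on an arbitrary codon state set:
# q_xy = pi_y * kappa^[transition] * omega^[nonsynonymous] for single-nt
# neighbours, 0 otherwise; diagonal set so rows sum to zero. `forbid_stops`
# zeroes rates into and out of stop codons (used for the protein-coding frame).
.m0_generator <- function(pi, kappa, omega, states, forbid_stops = FALSE) {
  ns <- .neighbour_structure(states)
  n <- length(states)
  R <- matrix(rep(as.numeric(pi), each = n), n, n)
  R[!ns$neighbour] <- 0
  R[ns$transition] <- R[ns$transition] * kappa
  R[ns$neighbour & !ns$synonymous] <- R[ns$neighbour & !ns$synonymous] * omega
  if (forbid_stops) {
    is_stop <- ns$aa == "*"
    R[is_stop, ] <- 0
    R[, is_stop] <- 0
  }
  diag(R) <- 0
  diag(R) <- -rowSums(R)
  dimnames(R) <- list(states, states)
  R
}

# Total substitution flux sum_x pi_x * (-q_xx); the M0 scaling divides by it.
.total_flux <- function(Q, pi) -sum(as.numeric(pi) * diag(Q))

#' Goldman-Yang (M0) codon substitution model
#'
#' Builds the continuous-time Markov generator of the M0 codon model on the 61
#' sense codons: for codons x != y differing at a single nucleotide position,
#' the rate is `q_xy = pi_y * kappa^[transition] * omega^[nonsynonymous]`,
#' zero for multi-nucleotide changes; transitions to stop codons are not
#' allowed inside functional proteins. The diagonal makes rows sum to zero and
#' the matrix is rescaled so the expected number of nucleotide substitutions
#' per codon per unit time is one. The model is reversible with stationary
#' distribution `pi`.
#'
#' @param usage equilibrium codon usage (a [codon_usage] vector or anything
#'   [codon_usage()] accepts).
#' @param kappa transition/transversion rate ratio (>= 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0); < 1 purifying,
#'   1 neutral, > 1 adaptive selection.
#' @param scale if `TRUE` (default) apply the substitutions-per-codon scaling.
#' @return object of class `codon_model` with elements `Q` (61x61 generator),
#'   `pi`, `kappa`, `omega`, `states`, and `scaling` (the factor divided out).
#' @examples
#' m <- codon_model(uniform_codon_usage(), kappa = 2, omega = 0.5)
#' m$Q["AAA", "AAG"]   # synonymous transition
#' @export
codon_model <- function(usage, kappa = 1, omega = 1, scale = TRUE) {
  usage <- codon_usage(usage)
  stopifnot(is.finite(kappa), kappa >= 0, is.finite(omega), omega >= 0)
  Q <- .m0_generator(usage, kappa, omega, SENSE_CODONS)
  scaling <- 1
  if (scale) {
    scaling <- .total_flux(Q, usage)
    if (scaling <= 0) stop("degenerate model: total substitution rate is zero")
    Q <- Q / scaling
  }
  structure(list(Q = Q, pi = usage, kappa = kappa, omega = omega,
                 states = SENSE_CODONS, scaling = scaling),
            class = "codon_model")
}

#' Rescale a generator to one expected substitution per codon per unit time
#'
#' Divides `Q` by the total flux `sum_x pi_x (-q_xx)` so that afterwards the
#' expected number of substitutions per codon per unit time equals one. The
#' result is invariant to any prior positive rescaling of `Q`.
#'
#' @param Q square generator matrix (rows sum to zero).
#' @param usage stationary weights over the states of `Q`.
#' @return rescaled generator.
#' @export
scale_rate_matrix <- function(Q, usage) {
  flux <- .total_flux(Q, usage)
  if (flux <= 0) stop("degenerate model: total substitution rate is zero")
  Q / flux
}

#' Evolutionary transition matrix P(t) = exp(Qt)
#'
#' @param x a `codon_model`, a `frame_model`, or a generator matrix.
#' @param t evolutionary time (expected substitutions per codon), >= 0.
#' @return row-stochastic matrix with the same state labels.
#' @export
transition_matrix <- function(x, t) {
  if (t < 0) stop("'t' must be >= 0")
  Q <- if (is.matrix(x)) x
       else if (inherits(x, c("codon_model", "frame_model"))) x$Q
       else stop("'x' must be a model object or a generator matrix")
  P <- as.matrix(Matrix::expm(Q * t))
  dimnames(P) <- dimnames(Q)
  P
}

#' Stationary distribution of a generator
#'
#' Solves `pi Q = 0`, `sum(pi) = 1` by a constrained linear least-squares
#' solve. States with zero total rate (unreachable, flagged by projection) are
#' assigned zero mass. Warns if the generator appears reducible on its support
#' and errors if the stationary distribution is not unique.
#'
#' @param x generator matrix or a `codon_model`/`frame_model`.
#' @return probability vector named by states.
#' @export
stationary_distribution <- function(x) {
  Q <- if (is.matrix(x)) x
       else if (inherits(x, c("codon_model", "frame_model"))) x$Q
       else stop("'x' must be a model object or a generator matrix")
  n <- nrow(Q)
  active <- rowSums(Q != 0) > 0
  Qa <- Q[active, active, drop = FALSE]
  na <- nrow(Qa)
  A <- rbind(t(Qa), rep(1, na))
  qrA <- qr(A)
  if (qrA$rank < na) stop("non-ergodic model: stationary distribution is not unique")
  p <- qr.coef(qrA, c(rep(0, na), 1))
  if (max(abs(t(Qa) %*% p)) > 1e-8)
    warning("generator may be reducible: stationary residual is large")
  if (any(p < -1e-8)) warning("stationary solve produced negative entries; clipping")
  p[p < 0] <- 0
  p <- p / sum(p)
  out <- stats::setNames(numeric(n), rownames(Q))
  out[active] <- p
  out
}

#' @export
print.codon_model <- function(x, ...) {
  cat("M0 codon substitution model (61 sense codons)\n")
  cat(sprintf("  kappa = %g, omega = %g; scaled to 1 substitution/codon/time\n",
              x$kappa, x$omega))
  cat(sprintf("  scaling factor divided out: %.6g\n", x$scaling))
  invisible(x)
}
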