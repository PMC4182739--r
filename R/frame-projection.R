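# Di-codon (Kronecker-sum) construction and marginalisation of the codon
# process into each of the six reading frames.
#
# Two adjacent frame +1 codons evolve independently, so the pair process has
# generator Q (+) Q = Q x I + I x Q on 61^2 = 3721 ordered sense-codon pairs
# with stationary distribution pi x pi. Every alternative-frame codon lies
# inside one such 6-nucleotide window, so the frame-f process is obtained by
# marginalising the pair process onto the frame-f sub-codon, weighting the
# unobserved flanks by their conditional stationary distribution given the
# sub-codon.

#' Di-codon generator of two adjacent codon sites
#'
#' Kronecker sum `Q (x) I + I (x) Q` over ordered pairs of sense codons (first
#' codon index varies slowest), with stationary distribution `pi (x) pi`.
#'
#' @param model a [codon_model].
#' @return object of class `dicodon_model`: sparse 3721x3721 generator `Q2`,
#'   stationary vector `pi2`, the 6-nucleotide `windows`, and `pairs` indices.
#' @export
dicodon_rate_matrix <- function(model) {
  stopifnot(inherits(model, "codon_model"))
  n <- length(model$states)
  Qs <- Matrix::Matrix(model$Q, sparse = TRUE)
  I <- Matrix::Diagonal(n)
  Q2 <- Matrix::kronecker(Qs, I) + Matrix::kronecker(I, Qs)
  i1 <- rep(seq_len(n), each = n)
  i2 <- rep(seq_len(n), times = n)
  windows <- paste0(model$states[i1], model$states[i2])
  pi2 <- as.numeric(model$pi)[i1] * as.numeric(model$pi)[i2]
  structure(list(Q2 = Q2, pi2 = pi2, windows = windows,
                 pairs = cbind(first = i1, second = i2),
                 states = model$states, model = model),
            class = "dicodon_model")
}

#' @export
print.dicodon_model <- function(x, ...) {
  cat("Di-codon generator over", length(x$windows), "ordered sense-codon pairs\n")
  invisible(x)
}

# Aggregate a stationary vector over di-codons onto frame-f sub-codons
# (64-codon container).
.frame_marginal <- function(pi2, sub_idx) {
  out <- numeric(64)
  agg <- rowsum(pi2, sub_idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Project the codon process into a reading frame
#'
#' Marginalises the di-codon generator onto the codon read by `frame`: for
#' frame-f codons x != y,
#' `q^f_xy = sum_d w(d|x) sum_{d' in y} Q2[d, d']` where d runs over di-codon
#' states whose frame-f sub-codon is x and `w(d|x)` is the conditional
#' stationary probability `(pi x pi)(d) / pi^f(x)`. Rows sum to zero by
#' construction and `pi^f` (the di-codon marginal) is stationary for `Q^f`.
#' Frame `+1` returns the input codon model's generator unchanged. States
#' with zero stationary support keep zero rows and are flagged `unreachable`.
#'
#' @param model a [codon_model], or a precomputed [dicodon_rate_matrix()]
#'   result.
#' @param frame a reading-frame label (see [FRAMES]).
#' @return object of class `frame_model`: `frame`, `states` (61 codons for
#'   frames +1/-1, 64 otherwise), generator `Q`, stationary `pi`, flagged
#'   `unreachable` states, and the model parameters `kappa`, `omega`.
#' @export
project_frame <- function(model, frame) {
  .check_frame(frame)
  cm <- if (inherits(model, "dicodon_model")) model$model else model
  if (frame == "+1") {
    return(structure(list(frame = "+1", states = cm$states, Q = cm$Q,
                          pi = stats::setNames(as.numeric(cm$pi), cm$states),
                          unreachable = character(0),
                          kappa = cm$kappa, omega = cm$omega),
                     class = "frame_model"))
  }
  dc <- if (inherits(model, "dicodon_model")) model
        else dicodon_rate_matrix(model)
  sub_idx <- match(frame_subcodon(dc$windows, frame), CODONS)
  nd <- length(sub_idx)
  pif64 <- .frame_marginal(dc$pi2, sub_idx)
  w <- ifelse(pif64[sub_idx] > 0, dc$pi2 / pif64[sub_idx], 0)
  W <- Matrix::sparseMatrix(i = seq_len(nd), j = sub_idx, x = w, dims = c(nd, 64))
  S <- Matrix::sparseMatrix(i = seq_len(nd), j = sub_idx, x = 1, dims = c(nd, 64))
  Qf64 <- as.matrix(Matrix::crossprod(W, dc$Q2 %*% S))
  states <- frame_states(frame)
  keep <- match(states, CODONS)
  Qf <- Qf64[keep, keep, drop = FALSE]
  pif <- pif64[keep]
  unreachable <- states[pif == 0]
  Qf[pif == 0, ] <- 0
  dimnames(Qf) <- list(states, states)
  structure(list(frame = frame, states = states, Q = Qf,
                 pi = stats::setNames(pif, states), unreachable = unreachable,
                 kappa = cm$kappa, omega = cm$omega),
            class = "frame_model")
}

#' Project into several frames at once
#'
#' @param model a [codon_model].
#' @param frames character vector of frame labels (default all six).
#' @return named list of [project_frame()] results, class `frame_models`.
#' @export
project_frames <- function(model, frames = FRAMES) {
  dc <- dicodon_rate_matrix(model)
  structure(stats::setNames(lapply(frames, function(f) project_frame(dc, f)),
                            frames),
            class = "frame_models")
}

#' Stationary distribution of a frame model
#'
#' Recomputes the stationary distribution from the projected generator `Q^f`
#' (left null vector); by construction it coincides with the direct marginal
#' of `pi (x) pi` stored in the frame model.
#'
#' @param fm a `frame_model`.
#' @return probability vector over the frame's states.
#' @export
frame_stationary <- function(fm) {
  stopifnot(inherits(fm, "frame_model"))
  stationary_distribution(fm$Q)
}

#' @export
print.frame_model <- function(x, ...) {
  cat(sprintf("Reading-frame model: frame %s, %d codon states\n",
              x$frame, length(x$states)))
  cat(sprintf("  kappa = %g, omega (frame +1 input) = %g\n", x$kappa, x$omega))
  if (length(x$unreachable))
    cat("  unreachable states:", paste(x$unreachable, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.frame_models <- function(x, ...) {
  cat("Reading-frame models for frames:", paste(names(x), collapse = " "), "\n")
  invisible(x)
}
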