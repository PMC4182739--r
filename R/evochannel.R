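# Top-level model object: the evolutionary channel of a protein-coding
# sequence and its projections into all six reading frames.

#' Evolutionary channel across all six reading frames
#'
#' Central constructor of the package. Builds the M0 codon substitution model
#' for the protein-coding frame +1 from a codon usage and the parameters
#' `kappa` (transition/transversion ratio) and `omega` (dN/dS), then projects
#' it through the di-codon construction into every requested reading frame.
#' The returned object bundles the codon model, the per-frame generators and
#' stationary distributions, and supports the usual model methods:
#' [print()], [summary()] (per-frame selection pressure), [coef()],
#' [predict()] (codon- or amino-acid-level transition matrices at a time t),
#' [plot()] (conditional entropy / mutual information versus time) and
#' [simulate()] (ancestral and evolved codon sequences).
#'
#' @param usage codon usage of the coding frame (anything [codon_usage()]
#'   accepts).
#' @param kappa transition/transversion rate ratio (default 1).
#' @param omega nonsynonymous/synonymous rate ratio in frame +1 (default 1).
#' @param frames frames to project (default all six).
#' @return object of class `evochannel` with elements `model` (the
#'   [codon_model]), `frames` (a `frame_models` list), `kappa`, `omega`.
#' @examples
#' ec <- evochannel(uniform_codon_usage(), kappa = 2, omega = 0.5)
#' summary(ec)
#' @export
evochannel <- function(usage, kappa = 1, omega = 1, frames = FRAMES) {
  model <- codon_model(usage, kappa = kappa, omega = omega)
  fms <- project_frames(model, frames)
  structure(list(model = model, frames = fms, kappa = kappa, omega = omega),
            class = "evochannel")
}

#' @export
print.evochannel <- function(x, ...) {
  cat("Evolutionary channel over reading frames:",
      paste(names(x$frames), collapse = " "), "\n")
  cat(sprintf("  M0 codon model, kappa = %g, omega = %g\n", x$kappa, x$omega))
  invisible(x)
}

#' @export
coef.evochannel <- function(object, ...) {
  c(kappa = object$kappa, omega = object$omega)
}

#' @export
summary.evochannel <- function(object, ...) {
  out <- list(coefficients = coef(object),
              selection = selection_summary(object))
  class(out) <- "summary.evochannel"
  out
}

#' @export
print.summary.evochannel <- function(x, ...) {
  cat("Evolutionary channel model\n")
  cat(sprintf("  kappa = %g, omega (frame +1) = %g\n",
              x$coefficients[["kappa"]], x$coefficients[["omega"]]))
  cat("\nSelection pressure per reading frame (omega^f = dN/dS):\n")
  sel <- x$selection
  print(data.frame(frame = sel$frame, d_n = signif(sel$d_n, 4),
                   d_s = signif(sel$d_s, 4), omega_f = signif(sel$omega, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Predict transition behaviour of the channel
#'
#' @param object an [evochannel].
#' @param t evolutionary time (expected substitutions per codon in frame +1).
#' @param frame reading frame.
#' @param what `"codon"` for the codon-level transition matrix `P^f(t)`,
#'   `"aa"` for the amino-acid channel.
#' @param ... unused.
#' @return a stochastic matrix (`what = "codon"`) or an [aa_channel].
#' @export
predict.evochannel <- function(object, t = 1, frame = "+1",
                               what = c("codon", "aa"), ...) {
  what <- match.arg(what)
  fm <- object$frames[[frame]]
  if (is.null(fm)) stop("frame ", frame, " was not projected")
  if (what == "codon") transition_matrix(fm, t) else aa_channel(fm, t)
}

#' Simulate sequences under the channel
#'
#' Draws `nsim` replicate ancestral sequences of `n` codons from the
#' stationary usage and evolves each through `P(t)`.
#'
#' @param object an [evochannel].
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param n sequence length in codons.
#' @param t evolutionary time.
#' @param ... unused.
#' @return list of `nsim` lists with elements `ancestral` and `evolved`.
#' @export
simulate.evochannel <- function(object, nsim = 1, seed = NULL, n = 1000,
                                t = 1, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- transition_matrix(object$model, t)
  replicate(nsim, {
    anc <- sample_stationary_sequence(n, object$model$pi)
    list(ancestral = anc, evolved = evolve_sequence(anc, P))
  }, simplify = FALSE)
}

#' Plot information measures of the channel over time
#'
#' Base-graphics curves of conditional entropy (genetic noise) or mutual
#' information (sequence similarity) per reading frame.
#'
#' @param x an [evochannel].
#' @param what `"entropy"` or `"mi"`.
#' @param times time grid.
#' @param ... passed to [graphics::matplot()].
#' @return the plotted matrix (times x frames), invisibly.
#' @export
plot.evochannel <- function(x, what = c("entropy", "mi"),
                            times = seq(0, 3, by = 0.25), ...) {
  what <- match.arg(what)
  col <- if (what == "entropy") "conditional_entropy" else "mutual_information"
  vals <- vapply(x$frames, function(fm) info_profile(fm, times)[[col]],
                 numeric(length(times)))
  graphics::matplot(times, vals, type = "l", lty = 1, lwd = 2,
                    xlab = "time t (substitutions per codon)",
                    ylab = if (what == "entropy")
                      "conditional entropy H(Y|X) [bits]"
                    else "mutual information I(X;Y) [bits]", ...)
  graphics::legend("right", legend = colnames(vals), lty = 1, lwd = 2,
                   col = seq_len(ncol(vals)))
  invisible(vals)
}

#' Half-information times across frames
#'
#' @param object an [evochannel] or `frame_models` list.
#' @param ... passed to [half_information_time()].
#' @return named numeric vector of times, one per frame.
#' @export
half_information_times <- function(object, ...) {
  fms <- if (inherits(object, "evochannel")) object$frames else object
  vapply(fms, half_information_time, numeric(1), ...)
}
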