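# Per-frame selection pressure: synonymous/nonsynonymous substitution fluxes
# and the dN/dS ratio omega^f induced in each reading frame.

# Synonymity mask over a state set: stop ("*") is treated as a 21st symbol, so
# stop<->stop changes are synonymous and stop<->amino-acid nonsynonymous.
.syn_masks <- function(states) {
  aa <- translate_codon(states)
  same <- outer(aa, aa, "==")
  diag(same) <- NA       # exclude x == y from both classes
  same
}

#' Synonymous and nonsynonymous substitution proportions
#'
#' The proportion of synonymous substitutions is the stationary flux over all
#' codon pairs x != y coding for the same amino acid,
#' `rho_syn = sum pi^f_x q^f_xy`; `rho_nonsyn` is the analogous sum over pairs
#' coding for different amino acids. Together they partition the total flux
#' `sum_x pi^f_x (-q^f_xx)`. In 64-state frames the stop label counts as a
#' 21st symbol.
#'
#' @param fm a `frame_model` (or any list with `Q`, `pi`, `states`).
#' @return named numeric vector `c(rho_syn, rho_nonsyn)`.
#' @export
substitution_proportions <- function(fm) {
  same <- .syn_masks(fm$states)
  Q <- fm$Q
  pi_f <- as.numeric(fm$pi)
  flux <- pi_f * Q
  rho_syn <- sum(flux[which(same)])
  rho_nonsyn <- sum(flux[which(!same)])
  c(rho_syn = rho_syn, rho_nonsyn = rho_nonsyn)
}

#' Neutral reference generator for site proportions
#'
#' Builds an M0-form generator with `omega = 1` on the frame's state space,
#' using the frame's stationary distribution `pi^f` and the shared
#' transition/transversion ratio `kappa` (the same in all reading frames).
#' It is used only to measure the proportions of synonymous and nonsynonymous
#' sites, so no scaling is applied. On state spaces containing stop codons the
#' stop transitions are kept (alternative-frame codons are not constrained to
#' functional proteins); frame +1's 61-state space contains no stops.
#'
#' @param fm a `frame_model`.
#' @param kappa transition/transversion ratio; defaults to the model's.
#' @return unscaled generator matrix on `fm$states`.
#' @export
reference_matrix <- function(fm, kappa = fm$kappa) {
  .m0_generator(fm$pi, kappa, omega = 1, states = fm$states)
}

#' Selection pressure omega^f in a reading frame
#'
#' Computes the nonsynonymous/synonymous rate ratio induced in a reading
#' frame: substitution proportions are taken from the frame generator, site
#' proportions from the `omega = 1` reference generator with the same `pi^f`
#' and `kappa`, and
#' `d_N = rho_N / rho_N^ref`, `d_S = rho_S / rho_S^ref`,
#' `omega^f = d_N / d_S`. Time and the scaling factors of the rate matrices
#' cancel in the ratio, and on frame +1 the input `omega` is recovered
#' exactly.
#'
#' @param fm a `frame_model`.
#' @param kappa transition/transversion ratio; defaults to the model's.
#' @return one-row `data.frame` (class `selection_summary`) with columns
#'   `frame`, `rho_syn`, `rho_nonsyn`, `rho_syn_ref`, `rho_nonsyn_ref`,
#'   `d_s`, `d_n`, `omega`. `omega` is `Inf` when `d_s` is zero.
#' @export
omega_per_frame <- function(fm, kappa = fm$kappa) {
  rho <- substitution_proportions(fm)
  ref <- list(Q = reference_matrix(fm, kappa), pi = fm$pi, states = fm$states)
  rho_ref <- substitution_proportions(ref)
  d_s <- rho[["rho_syn"]] / rho_ref[["rho_syn"]]
  d_n <- rho[["rho_nonsyn"]] / rho_ref[["rho_nonsyn"]]
  omega <- if (d_s > 0) d_n / d_s else Inf
  structure(data.frame(frame = fm$frame, rho_syn = rho[["rho_syn"]],
                       rho_nonsyn = rho[["rho_nonsyn"]],
                       rho_syn_ref = rho_ref[["rho_syn"]],
                       rho_nonsyn_ref = rho_ref[["rho_nonsyn"]],
                       d_s = d_s, d_n = d_n, omega = omega,
                       row.names = NULL),
            class = c("selection_summary", "data.frame"))
}

#' Selection summary across frames
#'
#' @param x a `frame_models` list (from [project_frames()]) or an
#'   [evochannel] object.
#' @return `data.frame` with one [omega_per_frame()] row per frame.
#' @export
selection_summary <- function(x) {
  fms <- if (inherits(x, "evochannel")) x$frames else x
  stopifnot(inherits(fms, "frame_models"))
  out <- do.call(rbind, lapply(fms, omega_per_frame))
  rownames(out) <- NULL
  out
}

#' omega^f over a grid of input omega values
#'
#' Recomputes the frame projections for each input `omega` and tabulates the
#' induced `omega^f` per frame — the data behind the selection-pressure
#' curves.
#'
#' @param usage codon usage of the protein-coding frame.
#' @param kappa transition/transversion ratio.
#' @param omega_grid numeric vector of input omega values.
#' @param frames frames to include.
#' @return `data.frame` with columns `omega_input`, one column per frame.
#' @export
omega_profile <- function(usage, kappa = 1, omega_grid = seq(0, 3, by = 0.5),
                          frames = FRAMES) {
  usage <- codon_usage(usage)
  rows <- lapply(omega_grid, function(w) {
    fms <- project_frames(codon_model(usage, kappa, w), frames)
    vapply(fms, function(fm) omega_per_frame(fm)$omega, numeric(1))
  })
  out <- data.frame(omega_input = omega_grid, do.call(rbind, rows),
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
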