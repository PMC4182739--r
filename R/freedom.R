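# Degrees of freedom of the genetic code across reading frames: how many
# distinct symbols can be written in an alternative frame while a fixed pair
# of frame +1 symbols is preserved.

#' Symbols encodable in an alternative frame for a fixed frame +1 pair
#'
#' Enumerates every di-codon (c1, c2) whose frame +1 translation is the pair
#' (a1, a2) — the stop label is a valid 21st symbol — and collects the
#' translations of the codon read by `frame` in the 6-nucleotide window. The
#' size of this set is the freedom left to an overlapping sequence in that
#' frame when the protein in frame +1 is fixed at (a1, a2).
#'
#' @param a1,a2 symbols from [AA_ALPHABET_STAR] (20 amino acids + `"*"`).
#' @param frame an alternative reading frame (not `"+1"`).
#' @return character vector of distinct encodable symbols.
#' @examples
#' encodable_set("M", "W", "-2")  # "H": the unique di-codon is ATGTGG
#' @export
encodable_set <- function(a1, a2, frame) {
  .check_frame(frame)
  if (frame == "+1") stop("'frame' must be an alternative frame")
  if (!a1 %in% AA_ALPHABET_STAR || !a2 %in% AA_ALPHABET_STAR)
    stop("a1 and a2 must be amino-acid one-letter codes or '*'")
  c1 <- CODONS[CODON_TABLE == a1]
  c2 <- CODONS[CODON_TABLE == a2]
  windows <- as.vector(outer(c1, c2, paste0))
  sort(unique(translate_codon(frame_subcodon(windows, frame))))
}

# round half up, the convention used for the printed 2-decimal table
.round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Mean coding degrees of freedom of a reading frame
#'
#' Arithmetic mean of `length(encodable_set(a1, a2, frame))` over all ordered
#' pairs of symbols. By default pairs range over the 21-symbol alphabet
#' (20 amino acids plus stop) and the stop label also counts as a distinct
#' encodable symbol; flags expose the nearby variants.
#'
#' @param frame an alternative reading frame.
#' @param include_stop_pairs include pairs containing the stop label
#'   (default `TRUE`, 21 x 21 pairs).
#' @param count_stop count the stop label among encodable symbols
#'   (default `TRUE`).
#' @return the unrounded mean count.
#' @export
mean_degrees_of_freedom <- function(frame, include_stop_pairs = TRUE,
                                    count_stop = TRUE) {
  syms <- if (include_stop_pairs) AA_ALPHABET_STAR else AA_ALPHABET
  counts <- outer(syms, syms, Vectorize(function(a1, a2) {
    s <- encodable_set(a1, a2, frame)
    if (!count_stop) s <- setdiff(s, "*")
    length(s)
  }))
  mean(counts)
}

#' Degrees-of-freedom table across alternative frames
#'
#' @param frames alternative frames to tabulate (default all five).
#' @param detail if `TRUE`, also return the per-pair count matrices.
#' @param ... passed to [mean_degrees_of_freedom()].
#' @return `data.frame` with columns `frame` and `mean` (rounded half-up to
#'   2 decimals); with `detail = TRUE`, a list with elements `table` and
#'   `detail`.
#' @export
degrees_of_freedom_table <- function(frames = ALT_FRAMES, detail = FALSE, ...) {
  means <- vapply(frames, mean_degrees_of_freedom, numeric(1), ...)
  tab <- data.frame(frame = frames, mean = .round2(means), row.names = NULL)
  if (!detail) return(tab)
  syms <- AA_ALPHABET_STAR
  det <- lapply(stats::setNames(frames, frames), function(f) {
    m <- outer(syms, syms, Vectorize(function(a1, a2)
      length(encodable_set(a1, a2, f))))
    dimnames(m) <- list(syms, syms)
    m
  })
  list(table = tab, detail = det)
}
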