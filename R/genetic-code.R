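# Nucleotide/codon alphabets, the standard genetic code and reading-frame algebra.
# Codon order is fixed lexicographic (AAA, AAC, ..., TTT) everywhere; all matrices
# carry codon labels in dimnames so state order can never drift silently.

#' Nucleotide alphabet
#'
#' The DNA alphabet in fixed order.
#' @export
NUCLEOTIDES <- c("A", "C", "G", "T")

.codon_grid <- expand.grid(n3 = NUCLEOTIDES, n2 = NUCLEOTIDES, n1 = NUCLEOTIDES,
                           stringsAsFactors = FALSE)

#' The 64 codons in lexicographic order
#'
#' `CODONS` lists all 64 codons (AAA, AAC, ..., TTT); `STOP_CODONS` the three
#' stops of the standard code; `SENSE_CODONS` the 61 sense codons in the same
#' lexicographic order. This ordering is the canonical state order for every
#' matrix in the package.
#' @export
CODONS <- paste0(.codon_grid$n1, .codon_grid$n2, .codon_grid$n3)

#' @rdname CODONS
#' @export
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @rdname CODONS
#' @export
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

# Standard genetic code (NCBI table 1; table 11 used for bacteria is identical
# for all 64 codons -- the tables differ only in initiation codons).
CODON_TABLE <- Biostrings::GENETIC_CODE[CODONS]

#' Amino-acid alphabets
#'
#' `AA_ALPHABET` holds the 20 amino acids (one-letter, alphabetical);
#' `AA_ALPHABET_STAR` appends the stop label `"*"` as a 21st symbol.
#' @export
AA_ALPHABET <- sort(unique(CODON_TABLE[CODON_TABLE != "*"]))

#' @rdname AA_ALPHABET
#' @export
AA_ALPHABET_STAR <- c(AA_ALPHABET, "*")

#' Reading-frame labels
#'
#' The six reading frames of double-stranded DNA relative to the protein-coding
#' frame `+1`: shifted forward frames `+2`, `+3` and the reverse-complement
#' frames `-1`, `-2`, `-3`.
#' @export
FRAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' @rdname FRAMES
#' @export
ALT_FRAMES <- c("+2", "+3", "-1", "-2", "-3")

.check_frame <- function(frame) {
  if (length(frame) != 1L || !frame %in% FRAMES)
    stop("'frame' must be one of ", paste(FRAMES, collapse = ", "))
  frame
}

.check_codons <- function(x) {
  x <- toupper(as.character(x))
  bad <- nchar(x) != 3L | !grepl("^[ACGT]{3}$", x)
  if (any(bad))
    stop("invalid codon(s): ", paste(unique(x[bad]), collapse = ", "))
  x
}

#' Translate codons with the standard genetic code
#'
#' @param codon character vector of codons (A/C/G/T triplets).
#' @return character vector of one-letter amino acids, `"*"` for stops.
#' @examples
#' translate_codon(c("ATG", "TAA", "AAA"))
#' @export
translate_codon <- function(codon) {
  unname(CODON_TABLE[.check_codons(codon)])
}

#' Complement and reverse complement
#'
#' `complement_seq()` complements each base; `reverse_complement()` additionally
#' reverses, so applying it twice is the identity.
#'
#' @param x character vector of DNA strings (any length).
#' @return character vector of the same lengths.
#' @examples
#' reverse_complement("ATG")  # "CAT"
#' @export
reverse_complement <- function(x) {
  comp <- complement_seq(x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(v) paste(rev(v), collapse = ""), character(1))
}

#' @rdname reverse_complement
#' @export
complement_seq <- function(x) {
  x <- toupper(as.character(x))
  if (any(grepl("[^ACGT]", x))) stop("sequence contains non-ACGT symbols")
  chartr("ACGT", "TGCA", x)
}

#' Extract the codon a reading frame sees in a 6-nucleotide window
#'
#' A di-codon window `n1..n6` (two adjacent frame `+1` codons) contains exactly
#' one complete codon of every reading frame. The frame conventions are:
#' `+1` reads positions 1-3, `+2` positions 2-4, `+3` positions 3-5; the
#' reverse-strand frames read the reverse complement of positions 4-6 (`-1`),
#' 3-5 (`-2`) and 2-4 (`-3`). In frame `-2` the first and second codon
#' positions of the `+1` codon fall onto its second and first positions.
#'
#' @param window character vector of 6-nucleotide windows.
#' @param frame one of `"+1", "+2", "+3", "-1", "-2", "-3"`.
#' @return character vector of codons.
#' @examples
#' frame_subcodon("ATGTGG", "-2")  # "CAC"
#' @export
frame_subcodon <- function(window, frame) {
  .check_frame(frame)
  window <- toupper(as.character(window))
  if (any(nchar(window) != 6L) || any(grepl("[^ACGT]", window)))
    stop("windows must be 6-nucleotide ACGT strings")
  switch(frame,
         "+1" = substr(window, 1L, 3L),
         "+2" = substr(window, 2L, 4L),
         "+3" = substr(window, 3L, 5L),
         "-1" = reverse_complement(substr(window, 4L, 6L)),
         "-2" = reverse_complement(substr(window, 3L, 5L)),
         "-3" = reverse_complement(substr(window, 2L, 4L)))
}

#' Codon state space of a reading frame
#'
#' Frame `+1` evolves over the 61 sense codons. Frame `-1` reads the reverse
#' complement of a `+1` codon, so its state space excludes the reverse
#' complements of the stops (TTA, CTA, TCA) and keeps 61 codons -- note it
#' does contain the stop codons themselves. The shifted frames `+2`, `+3`,
#' `-2`, `-3` straddle codon boundaries and use the full 64-codon container.
#'
#' @param frame a reading-frame label.
#' @return character vector of codon states (length 61 or 64).
#' @export
frame_states <- function(frame) {
  .check_frame(frame)
  switch(frame,
         "+1" = SENSE_CODONS,
         "-1" = setdiff(CODONS, reverse_complement(STOP_CODONS)),
         CODONS)
}
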