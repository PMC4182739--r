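# Shared TSV matrix I/O: square codon-labelled matrices (rate and transition
# matrices) with a header row and a leading label column.

#' Read and write codon-labelled matrices
#'
#' TSV dialect used for all Q and P matrices: a header row of codon labels,
#' one row per codon with its label in the first column, values at 10
#' significant digits.
#'
#' @param M square matrix with codon dimnames.
#' @param path file path.
#' @return `read_codon_matrix()` returns the labelled matrix;
#'   `write_codon_matrix()` returns `path` invisibly.
#' @export
write_codon_matrix <- function(M, path) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M),
            !is.null(rownames(M)), !is.null(colnames(M)))
  df <- data.frame(codon = rownames(M), signif(M, 12), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_codon_matrix
#' @export
read_codon_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- .check_codons(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- labels
  colnames(M) <- .check_codons(colnames(M))
  if (nrow(M) != ncol(M)) stop("matrix in ", path, " is not square")
  if (!identical(rownames(M), colnames(M)))
    stop("row and column codon labels disagree in ", path)
  storage.mode(M) <- "double"
  M
}
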