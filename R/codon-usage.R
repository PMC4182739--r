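# Codon-usage vectors: construction, extraction from annotated genomes, I/O.

#' Codon-usage vector over the 61 sense codons
#'
#' Validates and normalises a codon-usage vector: a named non-negative vector
#' over the sense codons summing to one. Vectors over all 64 codons are
#' accepted if the stop entries are zero. An optional floor can be applied for
#' downstream numerical stability (no pseudocounts by default).
#'
#' @param x named numeric vector (names are codons), length 61 or 64.
#' @param floor non-negative lower bound added to every sense codon before
#'   renormalising; default 0 (no flooring).
#' @return object of class `codon_usage`: named numeric vector over the 61
#'   sense codons in lexicographic order.
#' @export
codon_usage <- function(x, floor = 0) {
  if (is.null(names(x))) stop("codon usage must be a named vector")
  names(x) <- .check_codons(names(x))
  if (anyDuplicated(names(x))) stop("duplicated codon names")
  if (any(x < 0) || any(!is.finite(x))) stop("codon usage entries must be finite and >= 0")
  extra <- setdiff(names(x), CODONS)
  if (length(extra)) stop("unknown codons: ", paste(extra, collapse = ", "))
  if (any(x[names(x) %in% STOP_CODONS] > 0))
    stop("codon usage must place no mass on stop codons")
  out <- stats::setNames(numeric(61), SENSE_CODONS)
  common <- intersect(names(x), SENSE_CODONS)
  out[common] <- x[common]
  if (sum(out) <= 0) stop("codon usage sums to zero")
  out <- out + floor
  out <- out / sum(out)
  structure(out, class = "codon_usage")
}

#' @rdname codon_usage
#' @export
uniform_codon_usage <- function() {
  codon_usage(stats::setNames(rep(1 / 61, 61), SENSE_CODONS))
}

#' @export
print.codon_usage <- function(x, ...) {
  cat("Codon usage over", length(x), "sense codons\n")
  cat("  top 5:", paste(names(sort(unclass(x), decreasing = TRUE))[1:5], collapse = " "), "\n")
  cat("  zero-frequency codons:", sum(x == 0), "\n")
  invisible(x)
}

.as_char_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    first <- readLines(x, n = 1L)
    if (startsWith(first, ">"))
      return(as.character(Biostrings::readDNAStringSet(x)))
    if (startsWith(first, "LOCUS"))
      return(read_genbank_cds(x))
    stop("unrecognised sequence file format: ", x)
  }
  if (is.character(x)) return(x)
  stop("'x' must be CDS sequences (character/DNAStringSet) or a FASTA/GenBank path")
}

#' Codon usage from coding sequences
#'
#' Counts in-frame codons over a set of CDS (initiation codon included,
#' stop codons excluded, codons containing ambiguity codes skipped) and
#' normalises to a probability vector over the 61 sense codons. A CDS whose
#' length is not a multiple of three raises a warning and its trailing bases
#' are dropped.
#'
#' @param x CDS sequences: a character vector, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file of CDS / a
#'   GenBank flat file with CDS features (extracted strand-aware).
#' @param floor passed to [codon_usage()].
#' @return a [codon_usage] vector.
#' @examples
#' codon_usage_from_cds("ATGAAATAA")  # pi(ATG) = pi(AAA) = 0.5
#' @export
codon_usage_from_cds <- function(x, floor = 0) {
  seqs <- toupper(.as_char_seqs(x))
  if (!length(seqs)) stop("no coding sequences supplied")
  counts <- stats::setNames(numeric(64), CODONS)
  for (s in seqs) {
    n <- nchar(s)
    if (n %% 3L != 0L) {
      warning("CDS length ", n, " is not a multiple of 3; truncating trailing bases")
      n <- n - n %% 3L
    }
    if (n < 3L) next
    cods <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
    cods <- cods[grepl("^[ACGT]{3}$", cods)]     # skip ambiguity codes
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  counts[STOP_CODONS] <- 0
  if (sum(counts) == 0) stop("no unambiguous sense codons found in input")
  codon_usage(counts, floor = floor)
}

#' E. coli codon usage from the seqinr CDS collection
#'
#' Computes codon usage from the 999 Escherichia coli coding sequences bundled
#' with the seqinr package (`ec999`), a convenient offline stand-in for a
#' genome-wide E. coli codon-usage table.
#'
#' @param floor passed to [codon_usage()].
#' @return a [codon_usage] vector.
#' @export
ecoli_codon_usage <- function(floor = 0) {
  if (!requireNamespace("seqinr", quietly = TRUE))
    stop("ecoli_codon_usage() requires the 'seqinr' package")
  env <- new.env()
  utils::data("ec999", package = "seqinr", envir = env)
  seqs <- vapply(env$ec999, function(s) toupper(paste(s, collapse = "")), character(1))
  codon_usage_from_cds(seqs, floor = floor)
}

# --- GenBank flat-file CDS extraction (minimal parser) ----------------------

# Parse a GenBank location string (1-based inclusive) into a data.frame of
# (start, end, strand). Handles ranges, join(), complement() and order(),
# including complement(join(...)); partial markers (< >) are stripped.
.parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  rec <- function(s, strand) {
    if (grepl("^complement\\(", s))
      return(rec(sub("\\)$", "", sub("^complement\\(", "", s)), -strand))
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("\\)$", "", sub("^(join|order)\\(", "", s))
      depth <- cumsum((strsplit(inner, "")[[1]] == "(")) -
               cumsum((strsplit(inner, "")[[1]] == ")"))
      chars <- strsplit(inner, "")[[1]]
      cuts <- which(chars == "," & depth == 0)
      starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, length(chars))
      parts <- mapply(function(a, b) paste(chars[a:b], collapse = ""), starts, ends)
      return(do.call(rbind, lapply(parts, rec, strand = strand)))
    }
    m <- regmatches(s, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", s))[[1]]
    if (!length(m)) stop("cannot parse GenBank location: ", s)
    a <- as.integer(m[2]); b <- if (m[4] == "") a else as.integer(m[4])
    data.frame(start = a, end = b, strand = strand)
  }
  rec(loc, 1L)
}

.read_genbank <- function(path) {
  lines <- readLines(path)
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank file has no ORIGIN section: ", path)
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feat <- grep("^FEATURES", lines)
  cds_locs <- character(0)
  if (length(feat)) {
    block <- lines[(feat[1] + 1L):(ori[1] - 1L)]
    i <- 1L
    while (i <= length(block)) {
      if (grepl("^ {5}CDS +", block[i])) {
        loc <- sub("^ {5}CDS +", "", block[i])
        j <- i + 1L
        while (j <= length(block) && grepl("^ {21}", block[j]) &&
               !grepl("^ {21}/", block[j])) {
          loc <- paste0(loc, trimws(block[j])); j <- j + 1L
        }
        cds_locs <- c(cds_locs, loc)
        i <- j
      } else i <- i + 1L
    }
  }
  list(sequence = genome, cds_locations = cds_locs)
}

#' Read CDS sequences from a GenBank flat file
#'
#' Minimal GenBank reader: extracts the ORIGIN sequence and every CDS feature
#' location (strand-aware, `join`/`complement` supported; GenBank's 1-based
#' inclusive coordinates are converted internally) and returns the spliced
#' coding sequences in reading orientation.
#'
#' @param path path to a GenBank flat file.
#' @return character vector of CDS sequences.
#' @export
read_genbank_cds <- function(path) {
  gb <- .read_genbank(path)
  vapply(gb$cds_locations, function(loc) {
    parts <- .parse_gb_location(loc)
    segs <- vapply(seq_len(nrow(parts)), function(k)
      substr(gb$sequence, parts$start[k], parts$end[k]), character(1))
    s <- paste(segs, collapse = "")
    if (parts$strand[1] < 0) s <- reverse_complement(s)
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Genome length and GC content
#'
#' Computes sequence length (bp) and GC content (percent of unambiguous
#' A/C/G/T bases) for a genome provided as FASTA or GenBank.
#'
#' @param path path to a FASTA or GenBank file.
#' @return list with elements `length` (bp) and `gc` (percent).
#' @export
genome_stats <- function(path) {
  first <- readLines(path, n = 1L)
  genome <- if (startsWith(first, ">")) {
    paste(as.character(Biostrings::readDNAStringSet(path)), collapse = "")
  } else if (startsWith(first, "LOCUS")) {
    .read_genbank(path)$sequence
  } else stop("unrecognised genome file format: ", path)
  genome <- toupper(genome)
  counts <- table(strsplit(genome, "")[[1]])
  acgt <- sum(counts[intersect(names(counts), NUCLEOTIDES)])
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  list(length = nchar(genome), gc = 100 * gc / acgt)
}

# --- TSV I/O ----------------------------------------------------------------

#' Read and write codon-usage tables
#'
#' The on-disk format is a two-column TSV `codon<TAB>frequency` with a header
#' row, 61 rows in lexicographic codon order, frequencies at 10 significant
#' digits.
#'
#' @param usage a [codon_usage] vector.
#' @param path file path.
#' @return `read_codon_usage()` returns a [codon_usage] vector;
#'   `write_codon_usage()` returns `path` invisibly.
#' @export
write_codon_usage <- function(usage, path) {
  usage <- codon_usage(usage)
  df <- data.frame(codon = names(usage),
                   frequency = signif(as.numeric(usage), 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_codon_usage
#' @export
read_codon_usage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "frequency") %in% names(df)))
    stop("codon-usage TSV needs columns 'codon' and 'frequency'")
  codon_usage(stats::setNames(df$frequency, df$codon))
}
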