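# Shared fixtures and independent oracles for the test-suite.

# realistic non-uniform usage with a fixed seed
test_usage <- function(seed = 42) dirichlet_codon_usage(alpha = 2, seed = seed)

# E. coli codon usage (seqinr's bundled CDS collection); cached per session
ecoli_usage_cached <- local({
  u <- NULL
  function() {
    if (is.null(u)) u <<- suppressWarnings(ecoli_codon_usage())
    u
  }
})

# Truncated uniformization series for exp(Qt): an oracle independent of the
# Pade scaling-and-squaring route used by the implementation.
uniformization_expm <- function(Q, t, terms = 60) {
  n <- nrow(Q)
  lambda <- max(-diag(Q)) * 1.0001 + 1e-12
  A <- diag(n) + Q / lambda
  P <- matrix(0, n, n)
  term <- diag(n)
  w <- exp(-lambda * t)
  for (k in 0:terms) {
    if (k > 0) {
      term <- term %*% A
      w <- w * lambda * t / k
    }
    P <- P + w * term
  }
  P
}

# Brute-force frame projection: build the explicit di-codon generator by
# looping over single-codon changes, then marginalise with explicit
# per-state loops. Returns the 64x64 container matrix and marginal.
brute_force_projection <- function(model, frame) {
  n <- length(model$states)
  Q <- model$Q
  Q2 <- matrix(0, n * n, n * n)
  for (i in seq_len(n)) for (k in seq_len(n)) if (i != k) {
    rows <- (i - 1L) * n + seq_len(n)
    cols <- (k - 1L) * n + seq_len(n)
    Q2[cbind(rows, cols)] <- Q2[cbind(rows, cols)] + Q[i, k]
  }
  for (j in seq_len(n)) for (l in seq_len(n)) if (j != l) {
    rows <- (seq_len(n) - 1L) * n + j
    cols <- (seq_len(n) - 1L) * n + l
    Q2[cbind(rows, cols)] <- Q2[cbind(rows, cols)] + Q[j, l]
  }
  diag(Q2) <- -rowSums(Q2)
  i1 <- rep(seq_len(n), each = n)
  i2 <- rep(seq_len(n), times = n)
  windows <- paste0(model$states[i1], model$states[i2])
  sub <- match(frame_subcodon(windows, frame), CODONS)
  pi2 <- as.numeric(model$pi)[i1] * as.numeric(model$pi)[i2]
  pif <- vapply(1:64, function(k) sum(pi2[sub == k]), numeric(1))
  Qf <- matrix(0, 64, 64, dimnames = list(CODONS, CODONS))
  for (x in 1:64) {
    dx <- which(sub == x)
    if (!length(dx) || pif[x] == 0) next
    wgt <- pi2[dx] / pif[x]
    for (y in 1:64) {
      dy <- which(sub == y)
      Qf[x, y] <- sum(wgt * rowSums(Q2[dx, dy, drop = FALSE]))
    }
  }
  list(Q = Qf, pi = stats::setNames(pif, CODONS))
}

# Independent single-nucleotide neighbour enumeration via string surgery
# (different code path from the vectorised outer() masks in the package).
enumerate_neighbours <- function(codon) {
  out <- character(0)
  for (pos in 1:3) for (b in NUCLEOTIDES) {
    if (substr(codon, pos, pos) == b) next
    y <- codon
    substr(y, pos, pos) <- b
    out <- c(out, y)
  }
  out
}

is_transition_pair <- function(x, y) {
  d <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  pair <- sort(c(substr(x, d, d), substr(y, d, d)))
  identical(pair, c("A", "G")) || identical(pair, c("C", "T"))
}

# minimal GenBank flat file with two CDS (one on the reverse strand, one
# joined across two exons) for parser tests
write_test_genbank <- function(path) {
  genome <- paste0(
    "ATGAAACCCGGGTTTTAA",        # 1..18  forward CDS
    "GCGCGC",                    # 19..24 spacer
    "TTACATCATCAT",              # 25..36 revcomp CDS: ATGATGATGTAA
    "AT",                        # 37..38 spacer
    "ATGCCC", "GG", "AAATAG")    # join(39..44,47..52)
  n <- nchar(genome)
  lines <- c(
    sprintf("LOCUS       TESTSEQ %d bp    DNA     linear   BCT 01-JAN-2000", n),
    "DEFINITION  synthetic test genome.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    "     CDS             1..18",
    '                     /product="forward protein"',
    "     CDS             complement(25..36)",
    '                     /product="reverse protein"',
    "     CDS             join(39..44,47..52)",
    '                     /product="spliced protein"',
    "ORIGIN",
    paste0("        1 ", tolower(genome)),
    "//")
  writeLines(lines, path)
  genome
}
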