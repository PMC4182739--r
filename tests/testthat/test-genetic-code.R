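test_that("standard genetic code partitions the 64 codons as expected", {
  expect_length(CODONS, 64)
  expect_identical(CODONS, sort(CODONS))              # lexicographic
  expect_length(SENSE_CODONS, 61)
  expect_identical(STOP_CODONS, c("TAA", "TAG", "TGA"))
  aa <- translate_codon(CODONS)
  expect_equal(sum(aa == "*"), 3)
  expect_setequal(unique(aa[aa != "*"]), AA_ALPHABET)
  expect_true(all(table(aa[aa != "*"]) >= 1))          # every aa has a codon
  expect_identical(translate_codon(c("ATG", "TAA", "AAA")), c("M", "*", "K"))
  expect_error(translate_codon("AXG"), "invalid codon")
})

test_that("reverse complement is an involution with the expected images", {
  expect_identical(reverse_complement("ATG"), "CAT")
  expect_identical(reverse_complement("TAA"), "TTA")
  expect_identical(reverse_complement(reverse_complement(CODONS)), CODONS)
  expect_error(complement_seq("ATN"), "non-ACGT")
})

test_that("frame sub-codon extraction follows the fixed window convention", {
  w <- "ATGTGG"
  expect_identical(frame_subcodon(w, "+1"), "ATG")
  expect_identical(frame_subcodon(w, "+2"), "TGT")
  expect_identical(frame_subcodon(w, "+3"), "GTG")
  expect_identical(frame_subcodon(w, "-1"), "CCA")
  expect_identical(frame_subcodon(w, "-2"), "CAC")
  expect_identical(frame_subcodon(w, "-3"), "ACA")
  expect_error(frame_subcodon("ATG", "+2"), "6-nucleotide")
  expect_error(frame_subcodon(w, "+4"), "frame")
})

test_that("frame state spaces have the stated sizes and exclusions", {
  expect_identical(frame_states("+1"), SENSE_CODONS)
  expect_length(frame_states("-1"), 61)
  expect_false(any(c("TTA", "CTA", "TCA") %in% frame_states("-1")))
  expect_true(all(STOP_CODONS %in% frame_states("-1")))
  for (f in c("+2", "+3", "-2", "-3")) expect_length(frame_states(f), 64)
})

test_that("codon usage from CDS counts in-frame sense codons", {
  u <- codon_usage_from_cds("ATGAAATAA")
  expect_equal(u[["ATG"]], 0.5)
  expect_equal(u[["AAA"]], 0.5)
  expect_equal(sum(u), 1, tolerance = 1e-12)
  expect_equal(sum(u > 0), 2)

  u2 <- codon_usage_from_cds(c("ATGTGA", "ATGTAA"))   # stops excluded
  expect_equal(u2[["ATG"]], 1.0)

  expect_warning(u3 <- codon_usage_from_cds("ATGAAAC"), "multiple of 3")
  expect_equal(u3[["ATG"]], 0.5)

  u4 <- codon_usage_from_cds("ATGNNNAAA")              # ambiguity skipped
  expect_equal(u4[["ATG"]], 0.5)
  expect_equal(u4[["AAA"]], 0.5)

  expect_error(codon_usage_from_cds("NNN"), "no unambiguous")
  expect_error(codon_usage(c(ATG = 0.5, TAA = 0.5)), "stop")
})

test_that("GenBank CDS extraction is strand- and join-aware", {
  gb <- withr::local_tempfile(fileext = ".gb")
  genome <- write_test_genbank(gb)
  cds <- read_genbank_cds(gb)
  expect_identical(cds, c("ATGAAACCCGGGTTTTAA", "ATGATGATGTAA", "ATGCCCAAATAG"))

  st <- genome_stats(gb)
  expect_equal(st$length, nchar(genome))
  counts <- table(strsplit(genome, "")[[1]])
  expect_equal(st$gc, 100 * (counts[["G"]] + counts[["C"]]) / nchar(genome))

  u <- codon_usage_from_cds(gb)
  # 5 + 3 + 3 sense codons; ATG appears 1 + 3 + 1 = 5 times of 11
  expect_equal(u[["ATG"]], 5 / 11)
})

test_that("codon usage TSV round-trips and fixture FASTA plants composition", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  u <- test_usage(3)
  write_codon_usage(u, tmp)
  expect_equal(as.numeric(read_codon_usage(tmp)), as.numeric(u),
               tolerance = 1e-9)

  fa <- withr::local_tempfile(fileext = ".fasta")
  counts <- stats::setNames(rep(0L, 61), SENSE_CODONS)
  counts[c("ATG", "AAA", "GGC")] <- c(4L, 2L, 6L)
  synthetic_cds_fasta(counts, fa, n_records = 2, seed = 9)
  u2 <- codon_usage_from_cds(fa)
  expect_equal(u2[["GGC"]], 0.5)
  expect_equal(u2[["ATG"]], 4 / 12)
})
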