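test_that("di-codon generator is the Kronecker sum of two codon sites", {
  m <- codon_model(test_usage(1), kappa = 2, omega = 0.4)
  dc <- dicodon_rate_matrix(m)
  i <- function(c1, c2) (match(c1, m$states) - 1L) * 61L + match(c2, m$states)
  expect_equal(dc$Q2[i("AAA", "AAA"), i("AAA", "AAG")], m$Q["AAA", "AAG"])
  expect_equal(dc$Q2[i("AAA", "AAA"), i("AAG", "AAA")], m$Q["AAA", "AAG"])
  expect_equal(dc$Q2[i("AAA", "AAA"), i("AAG", "AAG")], 0)  # one event only
  set.seed(1)
  rows <- sample(3721, 100)
  expect_lt(max(abs(Matrix::rowSums(dc$Q2[rows, ]))), 1e-10)
  expect_equal(sum(dc$pi2), 1, tolerance = 1e-12)
})

test_that("optimised projection matches the brute-force di-codon oracle", {
  m <- codon_model(test_usage(7), kappa = 2, omega = 0.4)
  fm <- project_frame(m, "+2")
  oracle <- brute_force_projection(m, "+2")
  keep <- match(fm$states, CODONS)
  expect_lt(max(abs(oracle$Q[keep, keep] - fm$Q)), 1e-10)
  expect_equal(unname(fm$pi), unname(oracle$pi[keep]), tolerance = 1e-12)
})

test_that("projected generators are valid single-nucleotide processes", {
  m <- codon_model(test_usage(2), kappa = 3, omega = 0.2)
  fms <- project_frames(m)
  chars <- strsplit(CODONS, "")
  for (f in names(fms)) {
    fm <- fms[[f]]
    Q <- fm$Q
    expect_lt(max(abs(rowSums(Q))), 1e-8)
    expect_true(all(Q[row(Q) != col(Q)] >= -1e-12))
    # no multi-nucleotide jumps
    idx <- match(fm$states, CODONS)
    for (x in seq_along(idx)) {
      hs <- vapply(idx, function(y)
        sum(chars[[idx[x]]] != chars[[y]]), integer(1))
      expect_true(all(abs(Q[x, hs > 1]) < 1e-12))
    }
    # frame marginal is stationary for Q^f
    expect_lt(max(abs(as.numeric(fm$pi) %*% Q)), 1e-8)
  }
})

test_that("frame stationary distributions equal the di-codon marginals", {
  m <- codon_model(test_usage(3), kappa = 1.5, omega = 0.6)
  dc <- dicodon_rate_matrix(m)
  for (f in ALT_FRAMES) {
    fm <- project_frame(dc, f)
    sub <- frame_subcodon(dc$windows, f)
    marg <- vapply(fm$states, function(x) sum(dc$pi2[sub == x]), numeric(1))
    expect_equal(unname(fm$pi), unname(marg), tolerance = 1e-8)
    expect_equal(sum(fm$pi), 1, tolerance = 1e-10)
    # recomputing from the generator gives the same answer
    expect_equal(unname(frame_stationary(fm)), unname(fm$pi), tolerance = 1e-8)
  }
})

test_that("frame -1 is the reverse-complement relabelling of frame +1", {
  m <- codon_model(test_usage(5), kappa = 2, omega = 0.5)
  fm <- project_frame(m, "-1")
  expect_false(any(c("TTA", "CTA", "TCA") %in% fm$states))
  rc <- reverse_complement(fm$states)
  expect_equal(unname(fm$pi), as.numeric(m$pi)[match(rc, m$states)],
               tolerance = 1e-12)
  expect_equal(unname(fm$Q), unname(m$Q[match(rc, m$states), match(rc, m$states)]),
               tolerance = 1e-10)

  fu <- project_frame(codon_model(uniform_codon_usage()), "-1")
  expect_equal(unname(fu$pi), rep(1 / 61, 61), tolerance = 1e-12)
})

test_that("a neutral channel induces near-neutral selection in every frame", {
  # omega = 1, kappa = 1, pi = uniform over sense codons (iid uniform
  # nucleotides restricted to sense): residual frame asymmetry comes from
  # stop exclusion only
  fms <- project_frames(codon_model(uniform_codon_usage(), 1, 1))
  for (f in names(fms))
    expect_lt(abs(omega_per_frame(fms[[f]])$omega - 1), 0.2)
})
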