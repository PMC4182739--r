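test_that("substitution proportions partition the total flux", {
  m <- codon_model(test_usage(1), kappa = 2, omega = 0.4)
  for (f in FRAMES) {
    fm <- project_frame(m, f)
    rho <- substitution_proportions(fm)
    expect_true(all(rho >= 0))
    total <- -sum(as.numeric(fm$pi) * diag(fm$Q))
    expect_equal(unname(sum(rho)), total, tolerance = 1e-10)
  }
  m0 <- codon_model(test_usage(1), kappa = 2, omega = 0)
  rho0 <- substitution_proportions(project_frame(m0, "+1"))
  expect_equal(rho0[["rho_nonsyn"]], 0)
})

test_that("flux ratio matches a hand count of codon neighbours (uniform, neutral)", {
  # kappa = 1, omega = 1, uniform usage: every allowed single-nucleotide move
  # has the same rate, so rho_nonsyn / rho_syn equals the ratio of counts of
  # nonsynonymous to synonymous sense-codon neighbour pairs
  n_syn <- 0; n_nonsyn <- 0
  for (x in SENSE_CODONS) {
    for (y in enumerate_neighbours(x)) {
      if (y %in% STOP_CODONS) next
      if (translate_codon(x) == translate_codon(y)) n_syn <- n_syn + 1
      else n_nonsyn <- n_nonsyn + 1
    }
  }
  fm <- project_frame(codon_model(uniform_codon_usage(), 1, 1), "+1")
  rho <- substitution_proportions(fm)
  expect_equal(rho[["rho_nonsyn"]] / rho[["rho_syn"]], n_nonsyn / n_syn,
               tolerance = 1e-10)
})

test_that("the dN/dS procedure recovers the input omega exactly on frame +1", {
  u <- test_usage(6)
  for (w in c(0, 0.3, 1, 2.7)) {
    fm <- project_frame(codon_model(u, kappa = 3.1, omega = w), "+1")
    expect_equal(omega_per_frame(fm)$omega, w, tolerance = 1e-10)
  }
})

test_that("omega^f is invariant to rescaling the frame generator", {
  m <- codon_model(test_usage(2), kappa = 2, omega = 0.3)
  fm <- project_frame(m, "-2")
  ref <- omega_per_frame(fm)$omega
  fm$Q <- 13.7 * fm$Q
  expect_equal(omega_per_frame(fm)$omega, ref, tolerance = 1e-12)
})

test_that("reference matrices are valid and keep stop moves in 64-state frames", {
  m <- codon_model(test_usage(3), kappa = 2, omega = 0.4)
  fm2 <- project_frame(m, "+2")
  R <- reference_matrix(fm2)
  expect_lt(max(abs(rowSums(R))), 1e-10)
  stops <- match(STOP_CODONS, fm2$states)
  sense <- setdiff(seq_along(fm2$states), stops)
  expect_gt(sum(R[stops, sense]), 0)        # stop -> sense rates exist
  expect_gt(sum(R[sense, stops]), 0)

  # with input omega = 1 the frame +1 reference is the model generator up to scale
  m1 <- codon_model(test_usage(3), kappa = 2, omega = 1)
  fm1 <- project_frame(m1, "+1")
  R1 <- reference_matrix(fm1)
  ratio <- R1[R1 != 0] / fm1$Q[R1 != 0]
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("purifying selection in frame +1 protects frame -2 and only it", {
  u <- test_usage(8)   # realistic non-uniform usage
  sel <- selection_summary(evochannel(u, kappa = 1, omega = 0.3))
  w <- stats::setNames(sel$omega, sel$frame)
  expect_lt(w[["-2"]], 1)
  expect_true(all(w[c("+2", "+3", "-1", "-3")] > 1))

  sel3 <- selection_summary(evochannel(u, kappa = 1, omega = 3))
  w3 <- stats::setNames(sel3$omega, sel3$frame)
  expect_gt(w3[["-2"]], 1)
  expect_true(all(w3[c("+2", "+3", "-1", "-3")] < 1))
})

test_that("omega^{-2} increases with the input omega", {
  u <- test_usage(9)
  grid <- seq(0, 3, by = 0.5)
  prof <- omega_profile(u, kappa = 2, omega_grid = grid, frames = "-2")
  expect_true(all(diff(prof[["-2"]]) > 0))
})
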