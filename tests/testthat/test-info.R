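test_that("entropy and mutual information have the textbook extremes", {
  id <- diag(20)
  dimnames(id) <- list(AA_ALPHABET, AA_ALPHABET)
  expect_equal(conditional_entropy(id), 0)
  expect_equal(mutual_information(id), log2(20), tolerance = 1e-12)

  unif <- matrix(1 / 20, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  expect_equal(conditional_entropy(unif), log2(20), tolerance = 1e-12)
  expect_equal(mutual_information(unif), 0, tolerance = 1e-12)

  constant <- matrix(rep(c(0.7, 0.3, rep(0, 18)), each = 20), 20, 20)
  expect_equal(mutual_information(constant), 0, tolerance = 1e-12)
})

test_that("I = H(Y) - H(Y|X) holds on random stochastic matrices", {
  set.seed(3)
  for (rep in 1:5) {
    P <- matrix(stats::rgamma(20 * 20, 0.5), 20, 20)
    P <- P / rowSums(P)
    hy <- -sum(colMeans(P)[colMeans(P) > 0] * log2(colMeans(P)[colMeans(P) > 0]))
    expect_equal(mutual_information(P), hy - conditional_entropy(P),
                 tolerance = 1e-10)
  }
})

test_that("amino-acid channels are stochastic, start at identity, and mix", {
  m <- codon_model(test_usage(1), kappa = 1, omega = 0.3)
  for (f in c("+1", "-2", "+3")) {
    fm <- project_frame(m, f)
    ch0 <- aa_channel(fm, 0)
    expect_equal(unname(ch0$P), diag(length(ch0$alphabet)), tolerance = 1e-9)
    ch <- aa_channel(fm, 0.8)
    expect_lt(max(abs(rowSums(ch$P) - 1)), 1e-10)
    expect_true(all(ch$P >= -1e-12 & ch$P <= 1 + 1e-12))
    deep <- aa_channel(fm, 50)$P
    spread <- apply(deep, 2, function(col) diff(range(col)))
    expect_lt(max(spread), 1e-3)             # every row near the stationary dist
  }
})

test_that("noise accumulates and similarity decays monotonically in time", {
  m <- codon_model(test_usage(4), kappa = 1, omega = 0.3)
  times <- seq(0, 5, by = 0.25)
  for (f in FRAMES) {
    prof <- info_profile(project_frame(m, f), times)
    H <- prof$conditional_entropy
    I <- prof$mutual_information
    expect_equal(H[1], 0, tolerance = 1e-9)
    expect_equal(I[1], log2(20), tolerance = 1e-9)
    expect_true(all(H <= log2(20) + 1e-9))
    expect_true(all(diff(H) > -1e-9))
    expect_true(all(diff(I) < 1e-9))
  }
})

test_that("half-information time is the entropy crossing of log2(20)/2", {
  fm <- project_frame(codon_model(test_usage(2), kappa = 2, omega = 0.5), "+1")
  ht <- half_information_time(fm)
  expect_equal(conditional_entropy(aa_channel(fm, ht)), log2(20) / 2,
               tolerance = 1e-3)
  expect_error(half_information_time(fm, interval = c(0, 1e-6)),
               "not bracketed")
})

test_that("protected frames store information longest (E. coli usage)", {
  u <- ecoli_usage_cached()
  ht_pur <- half_information_times(project_frames(codon_model(u, 1, 0.3)))
  expect_gt(min(ht_pur[c("+1", "-2")]), max(ht_pur[c("+2", "+3", "-1", "-3")]))
  ht_adapt <- half_information_times(project_frames(codon_model(u, 1, 3)))
  expect_lt(max(ht_adapt[c("+1", "-2")]), min(ht_adapt[c("+2", "+3", "-1", "-3")]))

  # the protein-coding frame under purifying selection loses half its
  # information at t ~ 1 and under adaptive selection at t ~ 0.6; the
  # protected -2 frame at t ~ 0.9
  expect_equal(round(ht_pur[["+1"]], 1), 1.0, tolerance = 1e-9)
  expect_equal(round(ht_pur[["-2"]], 1), 0.9, tolerance = 1e-9)
  expect_equal(round(ht_adapt[["+1"]], 1), 0.6, tolerance = 1e-9)
})
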