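test_that("index normalization yields zero mean and unit population SD", {
  for (nm in c("tanford_hydrophobicity", "hopp_woods_hydrophilicity")) {
    h <- normalize_index(aa_index(nm))
    expect_length(h, 20)
    expect_equal(mean(h), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(h^2)), 1, tolerance = 1e-9)
  }
  expect_error(normalize_index(setNames(rep(3, 20), xylanact:::AA_ALPHABET)),
               class = "xyl_degenerate_index_error")
  expect_error(normalize_index(c(A = 1, C = 2)), class = "xyl_incomplete_table_error")
})

test_that("residue frequencies are relative counts over the canonical alphabet", {
  fa <- residue_frequencies("AAA")
  expect_equal(fa[["A"]], 1)
  expect_equal(sum(fa), 1)
  f4 <- residue_frequencies("ACDE")
  expect_equal(unname(f4[c("A", "C", "D", "E")]), rep(0.25, 4))
  expect_equal(sum(f4 > 0), 4)
  # lowercase input is uppercased before counting
  expect_equal(residue_frequencies("acde"), f4)
  expect_error(residue_frequencies("ACXDE"), class = "xyl_alphabet_error")
  # drop policy removes the offending residue and renormalizes over L-1
  expect_equal(residue_frequencies("ACXDE", nonstandard = "drop"), f4)
  withr::with_seed(11, {
    for (i in 1:20) expect_equal(sum(residue_frequencies(random_sequence(30))), 1)
  })
})

test_that("correlation factors: homopolymer closed form and length guard", {
  p2 <- pseaac_params(lambda = 2)
  tau <- correlation_factors(strrep("A", 10), p2)
  h1A <- normalize_index(aa_index("tanford_hydrophobicity"))[["A"]]
  h2A <- normalize_index(aa_index("hopp_woods_hydrophilicity"))[["A"]]
  expect_equal(tau, c(h1A^2, h2A^2, h1A^2, h2A^2))
  expect_error(correlation_factors("ACDEF", pseaac_params(lambda = 7)),
               class = "xyl_sequence_too_short_error")
  expect_length(correlation_factors("ACDEF", pseaac_params(lambda = 0)), 0)
})

test_that("correlation factors equal the naive double-loop oracle and are reversal-invariant", {
  p <- pseaac_params(lambda = 7)
  withr::with_seed(42, {
    for (i in 1:25) {
      s <- random_sequence(15)
      tau <- correlation_factors(s, p)
      expect_equal(tau, tau_oracle(s, p), tolerance = 1e-12)
      rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
      expect_equal(correlation_factors(rev_s, p), tau, tolerance = 1e-12)
    }
  })
})

test_that("PseAAC vector: dimension, normalization, and limiting cases", {
  p <- pseaac_params(lambda = 7)
  withr::with_seed(7, s <- random_sequence(120))
  v <- pseaac_vector(s, p)
  expect_length(v, 34)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_true(all(v[1:20] >= 0))

  # w = 0 collapses to plain composition padded with zeros
  v0 <- pseaac_vector(s, pseaac_params(lambda = 7, w = 0))
  expect_equal(unname(v0[1:20]), unname(residue_frequencies(s)))
  expect_equal(unname(v0[21:34]), rep(0, 14))

  # lambda = 0 is exactly the amino-acid composition
  expect_equal(unname(pseaac_vector(s, pseaac_params(lambda = 0))),
               unname(residue_frequencies(s)))
})

test_that("PseAAC vector properties hold on random sequences", {
  p <- pseaac_params(lambda = 5)
  withr::with_seed(123, {
    for (i in 1:20) {
      s <- random_sequence(sample(30:80, 1))
      v <- pseaac_vector(s, p)
      expect_equal(sum(v), 1, tolerance = 1e-9)
      # permuting residues leaves the composition block invariant up to the
      # shared normalizer (the correlation terms, and with them the
      # denominator, do change)
      perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
      vp <- pseaac_vector(perm, p)
      expect_equal(vp[1:20] / sum(vp[1:20]), v[1:20] / sum(v[1:20]),
                   tolerance = 1e-12)
      expect_equal(residue_frequencies(perm), residue_frequencies(s))
      # reversal leaves the full vector unchanged
      rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
      expect_equal(pseaac_vector(rev_s, p), v, tolerance = 1e-12)
    }
  })
})

test_that("a strongly negative correlation sum triggers the normalization error", {
  # alternating W/K has large negative hydrophilicity correlation at odd lags;
  # a large enough w drives the denominator below zero
  s <- strrep("WK", 20)
  expect_error(pseaac_vector(s, pseaac_params(lambda = 1, w = 100)),
               class = "xyl_normalization_error")
})

test_that("batch extraction preserves order, reports ids on error, handles empty input", {
  p <- pseaac_params(lambda = 7)
  withr::with_seed(5, seqs <- tibble::tibble(
    id = c("s1", "s2", "s1dup"),
    residues = c(random_sequence(60), random_sequence(60), "")
  ))
  seqs$residues[3] <- seqs$residues[1] # duplicate sequence
  fm <- extract_features(seqs, p)
  expect_equal(dim(fm), c(3, 35))
  expect_equal(fm$id, seqs$id)
  expect_equal(unlist(fm[3, -1]), unlist(fm[1, -1])) # identical rows for identical input

  empty <- extract_features(tibble::tibble(id = character(), residues = character()), p)
  expect_equal(dim(empty), c(0, 35))

  bad <- tibble::tibble(id = "oops", residues = "ACDEFGHIKLMNPQRSTVWYX")
  expect_error(extract_features(bad, p), "oops", class = "xyl_alphabet_error")
})

test_that("feature-matrix comparison flags perturbed columns at tolerance", {
  p <- pseaac_params(lambda = 3)
  withr::with_seed(9, seqs <- tibble::tibble(
    id = c("a", "b"), residues = c(random_sequence(50), random_sequence(50))
  ))
  fm <- extract_features(seqs, p)
  self <- compare_feature_matrices(fm, fm, tol = 1e-9)
  expect_true(self$pass)
  expect_equal(self$max_abs_dev, 0)

  pert <- fm
  pert$e5[2] <- pert$e5[2] + 2e-3
  cmp <- compare_feature_matrices(fm, pert, tol = 1e-3)
  expect_false(cmp$pass)
  expect_equal(cmp$by_column$feature[!cmp$by_column$pass], "e5")
  expect_error(compare_feature_matrices(fm, fm[-1, ]), class = "xyl_dimension_error")
})
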