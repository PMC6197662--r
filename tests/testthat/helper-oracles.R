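# Shared test helpers: independent brute-force oracles and tiny generators.

# A random canonical-residue sequence string.
random_sequence <- function(len) {
  paste(sample(xylanact:::AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# Naive double-loop correlation-factor oracle, independent of the package's
# vectorized path: walks every (i, i+k) pair explicitly.
tau_oracle <- function(residues, params) {
  chars <- strsplit(toupper(residues), "")[[1]]
  L <- length(chars)
  h1 <- normalize_index(aa_index("tanford_hydrophobicity"))
  h2 <- normalize_index(aa_index("hopp_woods_hydrophilicity"))
  tau <- numeric(2 * params$lambda)
  for (k in seq_len(params$lambda)) {
    s1 <- 0
    s2 <- 0
    for (i in seq_len(L - k)) {
      s1 <- s1 + h1[[chars[i]]] * h1[[chars[i + k]]]
      s2 <- s2 + h2[[chars[i]]] * h2[[chars[i + k]]]
    }
    tau[2 * k - 1] <- s1 / (L - k)
    tau[2 * k] <- s2 / (L - k)
  }
  tau
}

# Exhaustive KNN oracle: sorts ALL distances, no shortcuts.
knn_oracle_regress <- function(query_row, train, y, k) {
  d <- apply(train, 1, function(r) sqrt(sum((r - query_row)^2)))
  mean(y[order(d, seq_along(d))[seq_len(k)]])
}

# Small feature tibble for model tests: two well-separated Gaussian blobs.
make_blobs <- function(n_per = 10, sep = 50, seed = 99) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(stats::rnorm(n_per * 3), n_per, 3),
      matrix(stats::rnorm(n_per * 3, mean = sep), n_per, 3)
    )
  })
  colnames(X) <- c("f1", "f2", "f3")
  list(X = tibble::as_tibble(X),
       y = factor(rep(c("neg", "pos"), each = n_per)))
}
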