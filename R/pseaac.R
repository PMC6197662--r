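#' PseAAC encoding parameters
#'
#' Bundles the tunable quantities of the amphiphilic Pseudo Amino Acid
#' Composition encoding: the tier depth `lambda` (maximum residue separation
#' over which sequence-order correlation factors are computed; the feature
#' vector has `20 + 2*lambda` elements), the weight `w` balancing correlation
#' terms against composition terms, and the two hydropathy index tables.
#' Index tables are standardized to zero mean / unit population SD at
#' construction time.
#'
#' @param lambda Non-negative integer tier depth. Default 7, giving the
#'   34-element vector used for the xylanase study.
#' @param w Non-negative weight factor for the correlation terms. Default 0.05.
#' @param hydrophobicity,hydrophilicity Raw 20-entry named index vectors; see
#'   [aa_index()].
#' @param nonstandard Policy for residues outside the 20-letter canonical
#'   alphabet (B, J, O, U, X, Z, ...): `"error"` (default) rejects the
#'   sequence; `"drop"` removes the offending residues (this shortens the
#'   sequence and therefore changes all correlation denominators — use
#'   deliberately).
#' @return An object of class `pseaac_params`.
#' @examples
#' p <- pseaac_params(lambda = 7)
#' p$lambda
#' @export
pseaac_params <- function(lambda = 7L,
                          w = 0.05,
                          hydrophobicity = aa_index("tanford_hydrophobicity"),
                          hydrophilicity = aa_index("hopp_woods_hydrophilicity"),
                          nonstandard = c("error", "drop")) {
  nonstandard <- match.arg(nonstandard)
  if (length(lambda) != 1 || is.na(lambda) || lambda < 0 || lambda != round(lambda)) {
    abort("`lambda` must be a single non-negative integer", class = "xyl_param_error")
  }
  if (length(w) != 1 || is.na(w) || w < 0) {
    abort("`w` must be a single non-negative real", class = "xyl_param_error")
  }
  structure(
    list(
      lambda = as.integer(lambda),
      w = w,
      h1 = normalize_index(hydrophobicity),
      h2 = normalize_index(hydrophilicity),
      nonstandard = nonstandard
    ),
    class = "pseaac_params"
  )
}

#' @export
print.pseaac_params <- function(x, ...) {
  cat("<pseaac_params> lambda =", x$lambda, " w =", x$w,
      " (", 20L + 2L * x$lambda, "features )\n")
  invisible(x)
}

# Uppercase, validate against the canonical alphabet, apply the nonstandard
# policy. Returns a character vector of single residues.
prepare_residues <- function(residues, nonstandard = "error", id = NULL) {
  if (length(residues) != 1 || is.na(residues)) {
    abort("sequence must be a single non-NA string", class = "xyl_alphabet_error")
  }
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA_ALPHABET)
  if (any(bad)) {
    if (nonstandard == "drop") {
      chars <- chars[!bad]
    } else {
      abort(
        sprintf(
          "non-canonical residue(s) %s%s",
          paste(unique(chars[bad]), collapse = ", "),
          if (is.null(id)) "" else sprintf(" in sequence '%s'", id)
        ),
        class = "xyl_alphabet_error"
      )
    }
  }
  if (length(chars) == 0) {
    abort(
      sprintf("empty sequence%s", if (is.null(id)) "" else sprintf(" '%s'", id)),
      class = "xyl_alphabet_error"
    )
  }
  chars
}

#' Amino-acid composition of a sequence
#'
#' Relative frequency of each of the 20 canonical residues: the composition
#' block (first 20 elements, before normalization) of the PseAAC vector.
#'
#' @param residues A single amino-acid sequence string.
#' @param nonstandard See [pseaac_params()].
#' @return Named numeric 20-vector summing to 1, ordered as `AA_ALPHABET`.
#' @examples
#' residue_frequencies("ACDE")
#' @export
residue_frequencies <- function(residues, nonstandard = "error") {
  chars <- prepare_residues(residues, nonstandard)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  setNames(as.vector(counts) / length(chars), AA_ALPHABET)
}

#' Sequence-order correlation factors
#'
#' For each tier `k = 1..lambda` computes the amphiphilic correlation factors
#' between all residue pairs separated by `k` positions:
#' `tau[2k-1] = mean_i h1(E_i) * h1(E_{i+k})` (hydrophobicity tier) and
#' `tau[2k] = mean_i h2(E_i) * h2(E_{i+k})` (hydrophilicity tier), where `h1`
#' and `h2` are the standardized index tables and the mean runs over the
#' `L - k` pairs of a length-`L` sequence. Requires `lambda < L`.
#'
#' @param residues A single amino-acid sequence string.
#' @param params A [pseaac_params()] object.
#' @return Numeric vector `tau` of length `2 * lambda` (odd entries:
#'   hydrophobicity; even: hydrophilicity).
#' @examples
#' correlation_factors("MKVLAAGYWQNN", pseaac_params(lambda = 3))
#' @export
correlation_factors <- function(residues, params = pseaac_params()) {
  stopifnot(inherits(params, "pseaac_params"))
  chars <- prepare_residues(residues, params$nonstandard)
  L <- length(chars)
  lambda <- params$lambda
  if (lambda >= L) {
    abort(
      sprintf("sequence too short: lambda = %d requires length > %d (got %d)", lambda, lambda, L),
      class = "xyl_sequence_too_short_error"
    )
  }
  if (lambda == 0L) {
    return(numeric(0))
  }
  hv1 <- unname(params$h1[chars])
  hv2 <- unname(params$h2[chars])
  tau <- numeric(2L * lambda)
  for (k in seq_len(lambda)) {
    idx <- seq_len(L - k)
    tau[2L * k - 1L] <- mean(hv1[idx] * hv1[idx + k])
    tau[2L * k] <- mean(hv2[idx] * hv2[idx + k])
  }
  tau
}

#' Amphiphilic PseAAC feature vector
#'
#' Encodes one sequence as `20 + 2*lambda` numbers: the 20 residue
#' frequencies followed by the `2*lambda` weighted correlation factors, all
#' divided by the common normalizer `sum(f) + w * sum(tau)` so the whole
#' vector sums to 1.
#'
#' @inheritParams correlation_factors
#' @return Named numeric vector `e1..e{20+2*lambda}`.
#' @examples
#' v <- pseaac_vector(strrep("ACDEFGHIKL", 3), pseaac_params(lambda = 7))
#' length(v) # 34
#' sum(v)    # 1
#' @export
pseaac_vector <- function(residues, params = pseaac_params()) {
  stopifnot(inherits(params, "pseaac_params"))
  freqs <- residue_frequencies(residues, params$nonstandard)
  tau <- correlation_factors(residues, params)
  denom <- sum(freqs) + params$w * sum(tau)
  if (denom <= 0) {
    abort(
      sprintf("PseAAC normalizer is non-positive (%.6g): w * sum(tau) too negative", denom),
      class = "xyl_normalization_error"
    )
  }
  out <- c(freqs, params$w * tau) / denom
  names(out) <- paste0("e", seq_along(out))
  out
}

#' Extract a PseAAC feature matrix from a set of sequences
#'
#' Batch wrapper around [pseaac_vector()]. Input row order is preserved.
#'
#' @param sequences A data frame with columns `id` and `residues` (as returned
#'   by [read_fasta()] or [simulate_sequences()]).
#' @param params A [pseaac_params()] object.
#' @return A tibble with column `id` followed by `e1..e{20+2*lambda}`; one row
#'   per input sequence, in input order.
#' @examples
#' seqs <- tibble::tibble(id = c("a", "b"),
#'                        residues = c(strrep("ACDY", 10), strrep("KLMR", 10)))
#' extract_features(seqs, pseaac_params(lambda = 2))
#' @export
extract_features <- function(sequences, params = pseaac_params()) {
  stopifnot(is.data.frame(sequences))
  if (!all(c("id", "residues") %in% names(sequences))) {
    abort("`sequences` needs columns `id` and `residues`", class = "xyl_schema_error")
  }
  p <- 20L + 2L * params$lambda
  if (nrow(sequences) == 0) {
    empty <- matrix(numeric(0), nrow = 0, ncol = p,
                    dimnames = list(NULL, paste0("e", seq_len(p))))
    return(bind_cols(tibble(id = character(0)), as_tibble(empty)))
  }
  rows <- map2(sequences$id, sequences$residues, function(id, res) {
    v <- tryCatch(pseaac_vector(res, params), error = function(e) {
      abort(sprintf("sequence '%s': %s", id, conditionMessage(e)),
            class = class(e)[1], parent = e)
    })
    as_tibble(as.list(v))
  })
  bind_cols(tibble(id = as.character(sequences$id)), list_rbind(rows))
}

#' Compare two feature matrices column by column
#'
#' Reports the maximum absolute deviation per feature column and an overall
#' pass/fail at a tolerance. Intended for calibrating index tables and the
#' weight `w` against an externally computed reference matrix (e.g. a
#' published feature table).
#'
#' @param computed,reference Data frames with an `id` column and identical
#'   feature columns, same row order.
#' @param tol Maximum absolute deviation allowed for a pass.
#' @return A list with `by_column` (tibble: `feature`, `max_abs_dev`, `pass`),
#'   `max_abs_dev`, and `pass`.
#' @export
compare_feature_matrices <- function(computed, reference, tol = 1e-3) {
  stopifnot(is.data.frame(computed), is.data.frame(reference))
  feat_cols <- setdiff(names(computed), "id")
  if (!identical(dim(computed), dim(reference)) ||
      !identical(feat_cols, setdiff(names(reference), "id"))) {
    abort("feature matrices differ in shape or column names", class = "xyl_dimension_error")
  }
  by_col <- map_dbl(feat_cols, function(cl) {
    if (nrow(computed) == 0) 0 else max(abs(computed[[cl]] - reference[[cl]]))
  })
  report <- tibble(feature = feat_cols, max_abs_dev = by_col, pass = by_col <= tol)
  list(
    by_column = report,
    max_abs_dev = if (length(by_col)) max(by_col) else 0,
    pass = all(report$pass)
  )
}
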