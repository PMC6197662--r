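#' Amino-acid hydropathy index tables
#'
#' Raw (unstandardized) per-residue index values used to build the
#' sequence-order correlation factors of the amphiphilic PseAAC encoding.
#' `"tanford_hydrophobicity"` is the classic Tanford-type hydrophobicity
#' scale and `"hopp_woods_hydrophilicity"` the Hopp–Woods hydrophilicity
#' scale — the pair used by the original amphiphilic PseAAC formulation and
#' its web server. Any 20-entry named numeric vector can be swapped in via
#' [pseaac_params()].
#'
#' @param name One of `"tanford_hydrophobicity"`, `"hopp_woods_hydrophilicity"`.
#' @return A named numeric vector of length 20 (names are one-letter residue
#'   codes), attribute `index_name` carrying the table name.
#' @examples
#' aa_index("tanford_hydrophobicity")[["W"]]
#' @export
aa_index <- function(name = c("tanford_hydrophobicity", "hopp_woods_hydrophilicity")) {
  name <- match.arg(name)
  values <- switch(name,
    tanford_hydrophobicity = c(
      A =  0.62, R = -2.53, N = -0.78, D = -0.90, C =  0.29,
      Q = -0.85, E = -0.74, G =  0.48, H = -0.40, I =  1.38,
      L =  1.06, K = -1.50, M =  0.64, F =  1.19, P =  0.12,
      S = -0.18, T = -0.05, W =  0.81, Y =  0.26, V =  1.08
    ),
    hopp_woods_hydrophilicity = c(
      A = -0.5, R =  3.0, N =  0.2, D =  3.0, C = -1.0,
      Q =  0.2, E =  3.0, G =  0.0, H = -0.5, I = -1.8,
      L = -1.8, K =  3.0, M = -1.3, F = -2.5, P =  0.0,
      S =  0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5
    )
  )
  values <- values[AA_ALPHABET]
  attr(values, "index_name") <- name
  values
}

validate_index_table <- function(values, what = "index table") {
  if (!is.numeric(values) || is.null(names(values))) {
    abort(sprintf("%s must be a named numeric vector", what), class = "xyl_index_error")
  }
  missing <- setdiff(AA_ALPHABET, names(values))
  if (length(missing) > 0) {
    abort(
      sprintf("%s is incomplete: missing residues %s", what, paste(missing, collapse = ", ")),
      class = "xyl_incomplete_table_error"
    )
  }
  values[AA_ALPHABET]
}

#' Standardize an amino-acid index table
#'
#' Centers and scales a raw 20-entry index so that the mean over the 20
#' canonical residues is 0 and the population standard deviation (divisor 20)
#' is 1 — the standard conversion applied to hydropathy scales before they
#' enter the correlation factors, so that hydrophobicity and hydrophilicity
#' contribute on a common scale.
#'
#' @param raw Named numeric vector over the 20 canonical residues.
#' @return Named numeric vector, zero mean and unit population SD.
#' @examples
#' h1 <- normalize_index(aa_index("tanford_hydrophobicity"))
#' mean(h1) # ~0
#' @export
normalize_index <- function(raw) {
  values <- validate_index_table(raw, "raw index table")
  centered <- values - mean(values)
  pop_sd <- sqrt(mean(centered^2))
  if (pop_sd == 0) {
    abort(
      "degenerate index table: all 20 values are identical (zero spread)",
      class = "xyl_degenerate_index_error"
    )
  }
  out <- centered / pop_sd
  attr(out, "index_name") <- attr(raw, "index_name")
  out
}
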