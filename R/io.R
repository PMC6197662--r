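#' Read amino-acid sequences from a FASTA file
#'
#' Parses a (possibly line-wrapped) multi-record FASTA. The record id is the
#' first whitespace-delimited token of the header; residues are uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `residues`, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (any(Biostrings::width(set) == 0)) {
    abort(
      sprintf("empty FASTA record(s): %s",
              paste(ids[Biostrings::width(set) == 0], collapse = ", ")),
      class = "xyl_format_error"
    )
  }
  if (anyDuplicated(ids)) {
    abort(
      sprintf("duplicate FASTA id(s): %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      class = "xyl_format_error"
    )
  }
  tibble(id = ids, residues = unname(toupper(as.character(set))))
}

#' Write sequences to a FASTA file
#'
#' @param sequences A data frame with columns `id` and `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(setNames(sequences$residues, sequences$id))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

STRAIN_TABLE_COLS <- c("accession", "strain", "halo_mm", "class",
                       "act_pH4_T60", "act_pH4_T26", "act_pH6_T26")

#' Read a strain table (CSV or TSV)
#'
#' Expects the column contract `accession, strain, halo_mm, class,
#' act_pH4_T60, act_pH4_T26, act_pH6_T26`; empty activity cells mean the
#' strain was not assayed. Validates halo diameters (positive numbers), class
#' letters (L/M/H) and activities (non-negative), naming the offending row
#' and column on failure.
#'
#' @param path Path to a delimited file.
#' @param delim Field delimiter; inferred from the extension (`.tsv` vs
#'   `.csv`) when `NULL`.
#' @return A tibble shaped like [xylanase_strains()].
#' @export
read_strain_table <- function(path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(STRAIN_TABLE_COLS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("strain table is missing column(s): %s", paste(missing, collapse = ", ")),
          class = "xyl_schema_error")
  }
  if (nrow(raw) == 0) {
    warn("strain table has 0 rows")
  }
  num_col <- function(col, allow_na = FALSE, positive = FALSE) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(x) & !is.na(raw[[col]])
    if (!allow_na) bad <- bad | is.na(raw[[col]])
    if (positive) bad <- bad | (!is.na(x) & x <= 0)
    if (any(bad)) {
      abort(sprintf("invalid value in column '%s', row %d: '%s'",
                    col, which(bad)[1], raw[[col]][which(bad)[1]]),
            class = "xyl_schema_error")
    }
    x
  }
  cls <- raw$class
  bad_cls <- !(cls %in% c("L", "M", "H"))
  if (any(bad_cls)) {
    abort(sprintf("unknown class letter in row %d: '%s'", which(bad_cls)[1], cls[which(bad_cls)[1]]),
          class = "xyl_schema_error")
  }
  out <- tibble(
    accession = raw$accession,
    strain = raw$strain,
    halo_mm = num_col("halo_mm", positive = TRUE),
    real_class = factor(cls, levels = c("L", "M", "H"), ordered = TRUE),
    act_pH4_T60 = num_col("act_pH4_T60", allow_na = TRUE),
    act_pH4_T26 = num_col("act_pH4_T26", allow_na = TRUE),
    act_pH6_T26 = num_col("act_pH6_T26", allow_na = TRUE)
  )
  acts <- out[paste0("act_", CONDITION_LABELS)]
  if (any(unlist(acts) < 0, na.rm = TRUE)) {
    abort("activities must be non-negative", class = "xyl_schema_error")
  }
  n_cond <- rowSums(!is.na(as.matrix(acts)))
  if (any(!(n_cond %in% c(0L, 3L)))) {
    abort(sprintf("row %d has activities for only %d of 3 conditions",
                  which(!(n_cond %in% c(0L, 3L)))[1], n_cond[which(!(n_cond %in% c(0L, 3L)))[1]]),
          class = "xyl_schema_error")
  }
  out
}

#' Write a strain table (CSV or TSV)
#'
#' Inverse of [read_strain_table()]; `write_strain_table` then
#' `read_strain_table` is the identity.
#'
#' @param strains A tibble shaped like [xylanase_strains()].
#' @param path Output path (`.tsv` writes tab-separated, else comma).
#' @return `path`, invisibly.
#' @export
write_strain_table <- function(strains, path) {
  out <- tibble(
    accession = strains$accession,
    strain = strains$strain,
    halo_mm = strains$halo_mm,
    class = as.character(strains$real_class),
    act_pH4_T60 = strains$act_pH4_T60,
    act_pH4_T26 = strains$act_pH4_T26,
    act_pH6_T26 = strains$act_pH6_T26
  )
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(out, path, na = "")
  } else {
    readr::write_csv(out, path, na = "")
  }
  invisible(path)
}

#' Read a feature matrix
#'
#' Reads a per-sequence feature table: one id column followed by numeric
#' feature columns. Accepts the package's own CSV/TSV output
#' (`id, e1..e{20+2*lambda}`) and the layout of a published per-sequence
#' feature spreadsheet (XLSX via the readxl package, first column = sequence
#' id, remaining columns = feature values); feature columns are renamed to
#' `e1..eN` in file order.
#'
#' @param path Path to a CSV, TSV or XLSX file.
#' @return A tibble with `id` plus `e1..eN` numeric columns.
#' @export
read_feature_matrix <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      abort("reading .xlsx feature matrices needs the 'readxl' package",
            class = "xyl_format_error")
    }
    raw <- readxl::read_excel(path)
  } else {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    raw <- readr::read_delim(path, delim = delim, progress = FALSE, show_col_types = FALSE)
  }
  if (ncol(raw) < 2) {
    abort("feature matrix needs an id column plus at least one feature column",
          class = "xyl_schema_error")
  }
  feats <- raw[-1]
  if (!all(vapply(feats, is.numeric, logical(1)))) {
    abort("all feature columns must be numeric", class = "xyl_schema_error")
  }
  names(feats) <- paste0("e", seq_len(ncol(feats)))
  bind_cols(tibble(id = as.character(raw[[1]])), as_tibble(feats))
}

#' Write a feature matrix as CSV/TSV
#'
#' @param features A tibble with `id` plus feature columns (from
#'   [extract_features()]).
#' @param path Output path (`.tsv` writes tab-separated, else comma).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(features, path)
  } else {
    readr::write_csv(features, path)
  }
  invisible(path)
}
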