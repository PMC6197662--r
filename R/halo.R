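#' Halo-class thresholds
#'
#' Breakpoints for binning the halo zone diameter into the three activity
#' classes: below `low_upper` mm is Low, from `low_upper` to `high_upper` mm
#' (both inclusive) is Medium, above `high_upper` mm is High.
#' `selection_min` is the minimum diameter for a strain to be selected for
#' the quantitative assay; the default 4.0 mm selects exactly the 28 assayed
#' strains of the screening table (the looser "greater than 3.5 mm" rule is
#' available by setting `selection_min = 3.5 + 1e-9` or filtering manually).
#'
#' @param low_upper Upper edge of class L (mm), default 3.5.
#' @param high_upper Upper edge of class M (mm), default 5.5.
#' @param selection_min Minimum halo diameter (mm) for assay selection,
#'   default 4.
#' @return An object of class `halo_thresholds`.
#' @export
halo_thresholds <- function(low_upper = 3.5, high_upper = 5.5, selection_min = 4) {
  if (!(low_upper > 0 && low_upper < high_upper)) {
    abort("need 0 < low_upper < high_upper", class = "xyl_param_error")
  }
  structure(
    list(low_upper = low_upper, high_upper = high_upper, selection_min = selection_min),
    class = "halo_thresholds"
  )
}

#' Classify halo diameters into L/M/H
#'
#' Threshold rule for the clear zone a xylanase-secreting colony produces on
#' xylan agar: diameters below 3.5 mm are Low, 3.5–5.5 mm (inclusive on both
#' ends) Medium, above 5.5 mm High. Boundary diameters go to M, matching how
#' 3.5 mm halos are labelled in the screening table.
#'
#' @param halo_mm Numeric vector of halo diameters in millimetres, all > 0.
#' @param thresholds A [halo_thresholds()] object.
#' @return An ordered factor with levels L < M < H, same length as `halo_mm`.
#' @examples
#' classify_halo(c(2.9, 4.6, 6.5))
#' @export
classify_halo <- function(halo_mm, thresholds = halo_thresholds()) {
  stopifnot(inherits(thresholds, "halo_thresholds"))
  if (any(is.na(halo_mm)) || any(halo_mm <= 0)) {
    abort("halo diameters must be positive and non-missing", class = "xyl_domain_error")
  }
  cls <- ifelse(halo_mm < thresholds$low_upper, "L",
                ifelse(halo_mm > thresholds$high_upper, "H", "M"))
  factor(cls, levels = c("L", "M", "H"), ordered = TRUE)
}

#' Select strains for the quantitative assay
#'
#' Filters a strain table to the rows whose halo diameter reaches
#' `thresholds$selection_min`, preserving input order.
#'
#' @param strains A data frame with a `halo_mm` column (see
#'   [xylanase_strains()]).
#' @param thresholds A [halo_thresholds()] object.
#' @return The filtered tibble.
#' @examples
#' nrow(select_for_assay(xylanase_strains())) # 28
#' @export
select_for_assay <- function(strains, thresholds = halo_thresholds()) {
  stopifnot(is.data.frame(strains), inherits(thresholds, "halo_thresholds"))
  dplyr::filter(strains, .data$halo_mm >= thresholds$selection_min)
}
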