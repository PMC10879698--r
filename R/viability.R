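#' Fraction of image area above a viability threshold
#'
#' The viability proxy: the fraction of pixels whose intensity strictly
#' exceeds a hard threshold held constant per replicate batch (Calcein or
#' cytosolic GFP signal as a fraction of the total image area).
#'
#' @param img a `micrograph`.
#' @param threshold intensity threshold on the image's native scale.
#' @param min_object_px optional speckle filter: 8-connected above-threshold
#'   components smaller than this are dropped (default 0 = no cleanup).
#' @return A number in `[0, 1]`.
#' @export
coverage_fraction <- function(img, threshold, min_object_px = 0) {
  stopifnot(inherits(img, "micrograph"))
  if (threshold < 0 || threshold > max_intensity(img)) {
    stop("threshold outside the image's intensity range")
  }
  m <- img$pixels > threshold
  if (min_object_px > 0 && any(m)) {
    lab <- label_components_8(m)
    sz <- tabulate(lab[lab > 0])
    m <- array(lab %in% which(sz >= min_object_px), dim = dim(lab))
  }
  mean(m)
}

#' Mean coverage across fields of one well
#'
#' Wells are imaged at multiple fields (12 Calcein images or 55 time-lapse
#' images per well); the per-well readout is the arithmetic mean of the
#' per-field coverage fractions.
#'
#' @param fractions numeric vector of per-field coverage fractions.
#' @return Their arithmetic mean.
#' @export
aggregate_fields <- function(fractions) {
  if (!length(fractions)) stop("no fields to aggregate")
  if (any(fractions < 0 | fractions > 1)) {
    stop("coverage fractions must lie in [0, 1]")
  }
  mean(fractions)
}

#' Normalize coverage to baseline and vehicle control
#'
#' @param value coverage at the timepoint of interest.
#' @param baseline_value coverage at timepoint 0 of the experiment.
#' @param control_value coverage of the vehicle (DMSO) control at the same
#'   timepoint (optional).
#' @return A named list: `percent_of_baseline`, `percent_of_control`
#'   (`NA` when the corresponding denominator is missing or zero, with a
#'   warning).
#' @export
normalize_coverage <- function(value, baseline_value, control_value = NA) {
  pb <- if (is.na(baseline_value) || baseline_value == 0) {
    warning("zero or missing baseline coverage: percent_of_baseline is NA")
    NA_real_
  } else 100 * value / baseline_value
  pc <- if (is.na(control_value)) NA_real_ else if (control_value == 0) {
    warning("zero control coverage: percent_of_control is NA")
    NA_real_
  } else 100 * value / control_value
  list(percent_of_baseline = pb, percent_of_control = pc)
}
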