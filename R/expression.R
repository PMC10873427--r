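# Expression quantification: Western-blot densitometry normalization and
# comparative-CT (ddCT) qPCR fold changes.

#' Normalize a blot lane to its loading control
#'
#' Rhodopsin resolves as several bands (monomer, dimer, ...); their summed
#' intensity is divided by the GAPDH band of the same lane.
#'
#' @param rhodopsin_band_intensities Numeric vector of band intensities
#'   (a.u., >= 0), one per resolved species.
#' @param gapdh_intensity GAPDH band intensity (a.u., > 0).
#' @return Dimensionless normalized intensity.
#' @export
normalize_lane <- function(rhodopsin_band_intensities, gapdh_intensity) {
  if (any(rhodopsin_band_intensities < 0)) stop("band intensities must be >= 0")
  if (!is.finite(gapdh_intensity) || gapdh_intensity <= 0) {
    stop("gapdh_intensity must be > 0")
  }
  sum(rhodopsin_band_intensities) / gapdh_intensity
}

#' Express values relative to a control mean
#'
#' @param values Numeric vector of per-sample quantities.
#' @param control_mean Mean of the control group (> 0).
#' @return Values divided by the control mean.
#' @export
relative_to_control <- function(values, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0) {
    stop("control_mean must be > 0")
  }
  values / control_mean
}

#' Construct a qPCR sample
#'
#' @param ct_target Numeric CT replicates for the target gene, each in
#'   (0, 45).
#' @param ct_reference Named list of CT replicate vectors per reference gene
#'   (e.g. `list("18s_rrna" = c(...), gnat1 = c(...))`).
#' @param sample_id Label.
#' @return Object of class `qpcr_sample`.
#' @export
qpcr_sample <- function(ct_target, ct_reference, sample_id = NA_character_) {
  .check_ct <- function(ct, what) {
    if (length(ct) < 1 || any(ct <= 0) || any(ct >= 45)) {
      stop(what, " CT values must be in (0, 45) with >= 1 replicate")
    }
  }
  .check_ct(ct_target, "target")
  stopifnot(is.list(ct_reference), length(ct_reference) >= 1,
            !is.null(names(ct_reference)))
  for (g in names(ct_reference)) .check_ct(ct_reference[[g]], g)
  structure(list(ct_target = ct_target, ct_reference = ct_reference,
                 sample_id = sample_id),
            class = "qpcr_sample")
}

#' Comparative-CT fold change
#'
#' Replicates are averaged on the CT scale; then
#' dCT = mean(CT_target) - mean(CT_reference) per sample,
#' ddCT = dCT_sample - dCT_control, and fold = 2^(-ddCT) (amplification
#' efficiency fixed at 2).
#'
#' @param sample,control [qpcr_sample()] objects; both must carry the chosen
#'   reference gene.
#' @param reference Reference gene name (e.g. `"18s_rrna"` or `"gnat1"`).
#' @return List of class `relative_quantity`: `value` (fold), `basis`
#'   (`"ddct"`), `delta_delta_ct`.
#' @export
ddct_fold <- function(sample, control, reference) {
  stopifnot(inherits(sample, "qpcr_sample"), inherits(control, "qpcr_sample"))
  for (s in list(sample, control)) {
    if (!reference %in% names(s$ct_reference)) {
      stop("missing reference gene '", reference, "' in sample '", s$sample_id, "'")
    }
  }
  dct_s <- mean(sample$ct_target) - mean(sample$ct_reference[[reference]])
  dct_c <- mean(control$ct_target) - mean(control$ct_reference[[reference]])
  ddct <- dct_s - dct_c
  structure(list(value = 2^(-ddct), basis = "ddct", delta_delta_ct = ddct),
            class = "relative_quantity")
}
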