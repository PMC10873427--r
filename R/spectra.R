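#' Construct a fluorescence emission spectrum
#'
#' A spectrum is a wavelength grid (nm, strictly increasing) with matching
#' non-negative intensities in arbitrary fluorescence units, recorded at a
#' fixed excitation wavelength. Donor (mTq2) spectra are excited at 425 nm and
#' read out at 476 nm for the dequenching-based FRET efficiency.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @param intensities Numeric vector of intensities (a.u., >= 0), same length.
#' @param excitation Excitation wavelength in nm.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, excitation = 425) {
  stopifnot(is.numeric(wavelengths), is.numeric(intensities))
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities must have the same length")
  }
  if (length(wavelengths) < 2 || any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing with at least two points")
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative")
  }
  structure(
    list(wavelengths = as.numeric(wavelengths),
         intensities = as.numeric(intensities),
         excitation = excitation),
    class = "emission_spectrum"
  )
}

#' Donor intensity at a readout wavelength
#'
#' Linear interpolation of the emission spectrum onto the requested
#' wavelength; an exact grid hit returns the stored value.
#'
#' @param spectrum An [emission_spectrum()].
#' @param wavelength Readout wavelength in nm; must lie inside the grid range.
#'   Defaults to the 476 nm mTq2 donor readout.
#' @return Interpolated intensity (a.u.).
#' @export
donor_intensity <- function(spectrum, wavelength = 476) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  rng <- range(spectrum$wavelengths)
  if (wavelength < rng[1] || wavelength > rng[2]) {
    stop(sprintf("wavelength %g nm outside spectrum range [%g, %g]",
                 wavelength, rng[1], rng[2]))
  }
  stats::approx(spectrum$wavelengths, spectrum$intensities,
                xout = wavelength, method = "linear")$y
}

#' Bundle the three detergent conditions of one FRET sample
#'
#' One transfected sample is measured untreated, after mild detergent
#' (n-dodecyl-beta-D-maltoside, DM) which dissolves oligomers but not
#' aggregates, and after SDS which dissolves everything. All three donor
#' spectra must share one wavelength grid. The acceptor:donor expression
#' ratio (A:D) is measured upstream and carried as data.
#'
#' @param spectrum_untreated,spectrum_dm,spectrum_sds Donor-excitation
#'   [emission_spectrum()] objects on a common grid.
#' @param acceptor_donor_ratio Dimensionless A:D ratio, finite and >= 0.
#' @param sample_id Label for the sample.
#' @return An object of class `treatment_series`.
#' @export
treatment_series <- function(spectrum_untreated, spectrum_dm, spectrum_sds,
                             acceptor_donor_ratio, sample_id = NA_character_) {
  for (s in list(spectrum_untreated, spectrum_dm, spectrum_sds)) {
    stopifnot(inherits(s, "emission_spectrum"))
  }
  if (!identical(spectrum_untreated$wavelengths, spectrum_dm$wavelengths) ||
      !identical(spectrum_untreated$wavelengths, spectrum_sds$wavelengths)) {
    stop("all three spectra must share one wavelength grid")
  }
  if (!is.finite(acceptor_donor_ratio) || acceptor_donor_ratio < 0) {
    stop("acceptor_donor_ratio must be finite and >= 0")
  }
  structure(
    list(spectrum_untreated = spectrum_untreated,
         spectrum_dm = spectrum_dm,
         spectrum_sds = spectrum_sds,
         acceptor_donor_ratio = acceptor_donor_ratio,
         sample_id = sample_id),
    class = "treatment_series"
  )
}

#' FRET efficiencies from donor dequenching
#'
#' The SDS condition dissolves all rhodopsin complexes, so its donor emission
#' is the fully dequenched, zero-FRET reference F_SDS. With F_0 the untreated
#' and F_DM the DM-treated donor intensity at the readout wavelength:
#'
#' \deqn{E_{total} = (F_{SDS} - F_0) / F_{SDS}}
#' \deqn{E_{insensitive} = (F_{SDS} - F_{DM}) / F_{SDS}}
#' \deqn{E_{sensitive} = E_{total} - E_{insensitive}}
#'
#' DM-sensitive FRET (abolished by mild detergent) reports receptor
#' oligomers; DM-insensitive FRET (resistant to DM) reports aggregates. The
#' decomposition is conservative by construction. Small noise-induced
#' negative efficiencies are retained, not clipped.
#'
#' @param series A [treatment_series()].
#' @param wavelength Donor readout wavelength in nm (default 476).
#' @return A list of class `fret_point` with fields `acceptor_donor_ratio`,
#'   `e_total`, `e_dm_sensitive`, `e_dm_insensitive`, `sample_id`.
#' @export
compute_efficiencies <- function(series, wavelength = 476) {
  stopifnot(inherits(series, "treatment_series"))
  f0 <- donor_intensity(series$spectrum_untreated, wavelength)
  fdm <- donor_intensity(series$spectrum_dm, wavelength)
  fsds <- donor_intensity(series$spectrum_sds, wavelength)
  if (!is.finite(fsds) || fsds <= 0) {
    stop("invalid reference: SDS donor intensity at readout must be > 0")
  }
  e_total <- (fsds - f0) / fsds
  e_ins <- (fsds - fdm) / fsds
  structure(
    list(acceptor_donor_ratio = series$acceptor_donor_ratio,
         e_total = e_total,
         e_dm_sensitive = e_total - e_ins,
         e_dm_insensitive = e_ins,
         sample_id = series$sample_id),
    class = "fret_point"
  )
}

#' Tabulate FRET points from a list of treatment series
#'
#' @param series_list List of [treatment_series()] objects.
#' @param wavelength Donor readout wavelength in nm.
#' @return A tibble with one row per sample: `sample_id`,
#'   `acceptor_donor_ratio`, `e_total`, `e_dm_sensitive`, `e_dm_insensitive`.
#' @export
fret_points <- function(series_list, wavelength = 476) {
  pts <- lapply(series_list, compute_efficiencies, wavelength = wavelength)
  tibble::tibble(
    sample_id = vapply(pts, `[[`, character(1), "sample_id"),
    acceptor_donor_ratio = vapply(pts, `[[`, numeric(1), "acceptor_donor_ratio"),
    e_total = vapply(pts, `[[`, numeric(1), "e_total"),
    e_dm_sensitive = vapply(pts, `[[`, numeric(1), "e_dm_sensitive"),
    e_dm_insensitive = vapply(pts, `[[`, numeric(1), "e_dm_insensitive")
  )
}

#' Read / write a two-column spectrum TSV
#'
#' Format: header `wavelength_nm<TAB>intensity`, one row per grid point.
#'
#' @param path File path.
#' @param excitation Excitation wavelength recorded on read.
#' @return [emission_spectrum()] for the reader; invisibly `path` for the
#'   writer.
#' @export
read_spectrum_tsv <- function(path, excitation = 425) {
  d <- utils::read.delim(path, header = TRUE)
  emission_spectrum(d[[1]], d[[2]], excitation = excitation)
}

#' @rdname read_spectrum_tsv
#' @param spectrum An [emission_spectrum()] to write.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  d <- data.frame(wavelength_nm = spectrum$wavelengths,
                  intensity = spectrum$intensities)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
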