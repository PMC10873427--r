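# Seeded synthetic-data generators. Every generator draws from one explicit
# seeded stream (global random state untouched), records its ground truth in
# a manifest, and is a right-inverse of the matching analysis at zero noise.

.manifest <- function(generator, seed, parameters) {
  list(generator = generator, seed = seed, parameters = parameters)
}

#' Write / read a ground-truth manifest (JSON)
#'
#' @param manifest List with fields `generator`, `seed`, `parameters`.
#' @param path JSON file path.
#' @return The manifest (reader); invisibly `path` (writer).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Gaussian donor emission band on a fixed grid containing the 476 nm readout
.donor_band <- function(peak_intensity, grid = seq(450, 550, by = 2),
                        center = 476, width = 15) {
  emission_spectrum(grid, peak_intensity * exp(-(grid - center)^2 / (2 * width^2)),
                    excitation = 425)
}

#' Synthetic FRET treatment series from hyperbolic truth
#'
#' For each A:D ratio, draws the DM-sensitive and DM-insensitive target
#' efficiencies from their rectangular hyperbolas plus Gaussian noise, then
#' synthesizes consistent (untreated, DM, SDS) donor spectra - Gaussian
#' emission bands peaking at 476 nm - whose readout intensities realize those
#' efficiencies exactly under the dequenching formula, so the zero-noise
#' round trip through [compute_efficiencies()] is exact.
#'
#' @param emax_sensitive,ec50_sensitive,emax_insensitive,ec50_insensitive
#'   True hyperbola parameters per component (Emax in [0, 1], EC50 > 0).
#' @param ad_ratios A:D grid (>= 0).
#' @param noise_sd Gaussian noise SD added to each component efficiency.
#' @param seed Integer seed.
#' @param f_sds SDS-reference donor peak intensity (a.u.).
#' @return List: `series` (list of [treatment_series()]), `points` (tibble of
#'   realized efficiencies), `manifest`.
#' @export
make_fret_dataset <- function(emax_sensitive, ec50_sensitive,
                              emax_insensitive, ec50_insensitive,
                              ad_ratios = c(0.25, 0.5, 1, 2, 4, 8),
                              noise_sd = 0, seed = 1, f_sds = 1000) {
  stopifnot(emax_sensitive >= 0, emax_sensitive <= 1,
            emax_insensitive >= 0, emax_insensitive <= 1,
            ec50_sensitive > 0, ec50_insensitive > 0, noise_sd >= 0)
  hyper <- function(emax, ec50) emax * ad_ratios / (ec50 + ad_ratios)
  noise <- withr::with_seed(seed, list(
    sens = stats::rnorm(length(ad_ratios), 0, noise_sd),
    ins = stats::rnorm(length(ad_ratios), 0, noise_sd)))
  e_sens <- hyper(emax_sensitive, ec50_sensitive) + noise$sens
  e_ins <- hyper(emax_insensitive, ec50_insensitive) + noise$ins
  e_tot <- e_sens + e_ins
  if (any(e_tot > 1)) stop("infeasible efficiency combination: e_total > 1")

  series <- lapply(seq_along(ad_ratios), function(i) {
    treatment_series(
      spectrum_untreated = .donor_band(f_sds * (1 - e_tot[i])),
      spectrum_dm = .donor_band(f_sds * (1 - e_ins[i])),
      spectrum_sds = .donor_band(f_sds),
      acceptor_donor_ratio = ad_ratios[i],
      sample_id = sprintf("synthetic_%02d", i))
  })
  list(series = series,
       points = tibble::tibble(acceptor_donor_ratio = ad_ratios,
                               e_total = e_tot,
                               e_dm_sensitive = e_sens,
                               e_dm_insensitive = e_ins),
       manifest = .manifest("make_fret_dataset", seed,
                            list(emax_sensitive = emax_sensitive,
                                 ec50_sensitive = ec50_sensitive,
                                 emax_insensitive = emax_insensitive,
                                 ec50_insensitive = ec50_insensitive,
                                 ad_ratios = ad_ratios,
                                 noise_sd = noise_sd, f_sds = f_sds)))
}

#' Synthetic outer-nuclear-layer time courses
#'
#' Per-mouse nuclei counts are the one-phase-decay prediction plus Gaussian
#' noise, truncated at zero; the emitted series carry the per-age mean, SD,
#' and n used by the kinetics fits.
#'
#' @param rates Named vector of true rate constants k (month^-1), one per
#'   series.
#' @param y0 Shared age-zero count (default 21 nuclei).
#' @param plateau Fixed floor (default 1).
#' @param ages Sampling ages in months (default 2 weeks, 1, 3, 6 months).
#' @param n_mice Mice per age (default 6).
#' @param noise_sd Per-mouse count SD (default 1 nucleus).
#' @param seed Integer seed.
#' @return List: `mice` (long tibble series/age/mouse/count), `series`
#'   (named list of data frames with per-age means, as
#'   [fit_one_phase_decay()] expects), `summary` (tibble with mean/sd/n),
#'   `manifest`.
#' @export
make_onl_series <- function(rates, y0 = 21, plateau = 1,
                            ages = c(0.5, 1, 3, 6), n_mice = 6,
                            noise_sd = 1, seed = 1) {
  stopifnot(all(rates >= 0), noise_sd >= 0, plateau <= y0, all(ages > 0))
  if (is.null(names(rates))) names(rates) <- paste0("series_", seq_along(rates))
  mice <- withr::with_seed(seed, do.call(rbind, lapply(names(rates), function(nm) {
    mu <- .decay_predict(y0, rates[[nm]], plateau, rep(ages, each = n_mice))
    data.frame(series = nm,
               age = rep(ages, each = n_mice),
               mouse = rep(seq_len(n_mice), times = length(ages)),
               count = pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd)))
  })))
  summ <- mice |>
    dplyr::group_by(.data$series, .data$age) |>
    dplyr::summarise(value = mean(.data$count), sd = stats::sd(.data$count),
                     n = dplyr::n(), .groups = "drop")
  series <- lapply(split(summ, summ$series), function(d) {
    data.frame(age = d$age, value = d$value)
  })[names(rates)]
  list(mice = tibble::as_tibble(mice),
       series = series,
       summary = summ,
       manifest = .manifest("make_onl_series", seed,
                            list(rates = as.list(rates), y0 = y0,
                                 plateau = plateau, ages = ages,
                                 n_mice = n_mice, noise_sd = noise_sd)))
}

#' Correlated two-channel image pair
#'
#' Gaussian fields with specified population correlation rho, shifted and
#' scaled to non-negative intensities (offset 10 population SDs above zero,
#' with a floor at 0 as a guard; at that offset clipping is negligible).
#'
#' @param rho Target population correlation, |rho| <= 1.
#' @param size Image dimensions (rows, cols).
#' @param seed Integer seed.
#' @param mean,sd Intensity offset and scale.
#' @return List: `a`, `b` ([channel_image()]), `manifest`.
#' @export
make_coloc_pair <- function(rho, size = c(256, 256), seed = 1,
                            mean = 1000, sd = 100) {
  stopifnot(abs(rho) <= 1)
  z <- withr::with_seed(seed, list(
    z1 = matrix(stats::rnorm(prod(size)), size[1], size[2]),
    z3 = matrix(stats::rnorm(prod(size)), size[1], size[2])))
  z1 <- z$z1
  z2 <- rho * z$z1 + sqrt(1 - rho^2) * z$z3
  to_img <- function(z, label) {
    channel_image(pmax(mean + sd * z, 0), pixel_size = 0.1, channel_label = label)
  }
  list(a = to_img(z1, "receptor_yfp"),
       b = to_img(z2, "er_marker"),
       manifest = .manifest("make_coloc_pair", seed,
                            list(rho = rho, size = size, mean = mean, sd = sd)))
}

#' Synthetic ERG amplitude sweep
#'
#' Model prediction (standard or biphasic dose-response) plus Gaussian noise
#' on the amplitudes.
#'
#' @param truth Named list of true parameters: `r_max`, `log_ka`, and for the
#'   biphasic model also `log_kb` and `f`.
#' @param model `"standard"` or `"biphasic"`.
#' @param intensities Positive increasing flash-intensity grid (cd s/m^2).
#' @param noise_sd Amplitude noise SD (uV).
#' @param seed Integer seed.
#' @param wave,regime Passed to [erg_sweep()].
#' @return List: `sweep` ([erg_sweep()]), `manifest`.
#' @export
make_erg_sweep <- function(truth, model = c("standard", "biphasic"),
                           intensities = 10^seq(-3, 1.3, length.out = 9),
                           noise_sd = 0, seed = 1,
                           wave = "a", regime = "scotopic") {
  model <- match.arg(model)
  stopifnot(all(intensities > 0), all(diff(intensities) > 0), noise_sd >= 0)
  mu <- .dr_predict(truth, log10(intensities), model)
  amp <- mu + withr::with_seed(seed,
                               stats::rnorm(length(mu), 0, noise_sd))
  list(sweep = erg_sweep(intensities, amp, wave = wave, regime = regime),
       manifest = .manifest("make_erg_sweep", seed,
                            list(truth = truth, model = model,
                                 intensities = intensities,
                                 noise_sd = noise_sd)))
}

#' Synthetic stained field with a known particle count
#'
#' Disjoint bright disks on a noisy background. Centers are placed by
#' rejection sampling with a retry cap; disks keep a 2-pixel clearance from
#' each other and a 1-pixel clearance from the border so they stay separate
#' components at either connectivity.
#'
#' @param n_particles Number of disks.
#' @param radius_range Disk radius range in pixels.
#' @param intensity Disk intensity; `background` the background level;
#'   `noise_sd` Gaussian background noise SD.
#' @param size Image dimensions.
#' @param pixel_size um per pixel (default gives a 317 x 317 um field).
#' @param stain,region Passed to [field_image()].
#' @param seed Integer seed.
#' @param max_tries Placement retry cap before a capacity error.
#' @return List: `image` ([field_image()]), `manifest` (records centers,
#'   radii, and the exact count).
#' @export
make_field_image <- function(n_particles, radius_range = c(3, 6),
                             intensity = 200, background = 20, noise_sd = 5,
                             size = c(256, 256), pixel_size = 317 / 256,
                             stain = "TUNEL", region = "superior",
                             seed = 1, max_tries = 5000) {
  stopifnot(n_particles >= 0, noise_sd >= 0, intensity > background)
  drawn <- withr::with_seed(seed, {
    px <- matrix(background + stats::rnorm(prod(size), 0, noise_sd),
                 size[1], size[2])
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0
    while (nrow(centers) < n_particles) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("capacity error: could not place ", n_particles,
             " disjoint disks in ", max_tries, " tries")
      }
      r <- stats::runif(1, radius_range[1], radius_range[2])
      cx <- stats::runif(1, r + 1, size[1] - r - 1)
      cy <- stats::runif(1, r + 1, size[2] - r - 1)
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
        if (any(d < radii + r + 2)) next
      }
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
    }
    list(px = px, centers = centers, radii = radii)
  })
  px <- drawn$px; centers <- drawn$centers; radii <- drawn$radii
  if (n_particles > 0) {
    rowg <- matrix(seq_len(size[1]), size[1], size[2])
    colg <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
    for (i in seq_len(n_particles)) {
      inside <- (rowg - centers[i, 1])^2 + (colg - centers[i, 2])^2 <= radii[i]^2
      px[inside] <- intensity
    }
  }
  list(image = field_image(px, pixel_size, stain = stain, region = region),
       manifest = .manifest("make_field_image", seed,
                            list(n_particles = n_particles,
                                 centers = centers, radii = radii,
                                 radius_range = radius_range,
                                 intensity = intensity,
                                 background = background,
                                 noise_sd = noise_sd, size = size,
                                 pixel_size = pixel_size)))
}

#' Synthetic comparative-CT qPCR table
#'
#' CT values are constructed so that the noiseless ddCT fold reproduces the
#' requested true fold exactly: the sample's target CT is offset from the
#' control's by -log2(fold).
#'
#' @param true_folds Named numeric vector of true folds (> 0) per sample,
#'   relative to the control.
#' @param ct_noise_sd Gaussian CT replicate noise SD (cycles).
#' @param replicates Technical replicates per gene.
#' @param seed Integer seed.
#' @param reference Reference gene name.
#' @param ct_reference_base,ct_target_base Baseline CT levels (cycles).
#' @return List: `samples` (named list of [qpcr_sample()]), `control`
#'   ([qpcr_sample()]), `manifest`.
#' @export
make_qpcr_table <- function(true_folds, ct_noise_sd = 0, replicates = 3,
                            seed = 1, reference = "18s_rrna",
                            ct_reference_base = 12, ct_target_base = 22) {
  stopifnot(all(true_folds > 0), ct_noise_sd >= 0, replicates >= 1)
  if (is.null(names(true_folds))) {
    names(true_folds) <- paste0("sample_", seq_along(true_folds))
  }
  draw <- function(mu) mu + stats::rnorm(replicates, 0, ct_noise_sd)
  mk <- function(target_mu, id) {
    qpcr_sample(ct_target = draw(target_mu),
                ct_reference = stats::setNames(list(draw(ct_reference_base)),
                                               reference),
                sample_id = id)
  }
  built <- withr::with_seed(seed, {
    control <- mk(ct_target_base, "control")
    samples <- lapply(names(true_folds), function(nm) {
      mk(ct_target_base - log2(true_folds[[nm]]), nm)
    })
    list(control = control, samples = samples)
  })
  control <- built$control
  samples <- built$samples
  names(samples) <- names(true_folds)
  list(samples = samples, control = control,
       manifest = .manifest("make_qpcr_table", seed,
                            list(true_folds = as.list(true_folds),
                                 ct_noise_sd = ct_noise_sd,
                                 replicates = replicates,
                                 reference = reference,
                                 ct_reference_base = ct_reference_base,
                                 ct_target_base = ct_target_base)))
}
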