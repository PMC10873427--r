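#!/usr/bin/env Rscript
# Generate the seeded synthetic study inputs for every downstream stage and
# write them, with their ground-truth manifests, under results/synthetic/.
# All later scripts regenerate from the same seeds, so this step is
# documentation of the inputs rather than a hard dependency.

suppressMessages(library(retinaggr))
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20240216

# FRET: an oligomer-forming (DM-sensitive) and an aggregate-forming
# (DM-insensitive) component, six A:D ratios, efficiency noise sd 0.01
fret <- make_fret_dataset(0.30, 1.5, 0.10, 1.5, noise_sd = 0.01, seed = seed)
write_manifest(fret$manifest, file.path(out, "fret_manifest.json"))
utils::write.csv(fret$points, file.path(out, "fret_points.csv"),
                 row.names = FALSE)
for (s in fret$series) {
  write_spectrum_tsv(s$spectrum_untreated,
                     file.path(out, paste0(s$sample_id, "_untreated.tsv")))
  write_spectrum_tsv(s$spectrum_dm,
                     file.path(out, paste0(s$sample_id, "_dm.tsv")))
  write_spectrum_tsv(s$spectrum_sds,
                     file.path(out, paste0(s$sample_id, "_sds.tsv")))
}

# ONL time courses at the reference superior-retina rates, n = 6 mice,
# per-mouse noise of one nucleus
rates <- with(subset(onl_decay_rates(), region == "superior" &
                       genotype != "B6"),
              stats::setNames(k, genotype))
onl <- make_onl_series(rates, noise_sd = 1, seed = seed)
write_manifest(onl$manifest, file.path(out, "onl_manifest.json"))
utils::write.csv(onl$mice, file.path(out, "onl_mice.csv"), row.names = FALSE)

# ERG sweeps: control and a reduced-Rmax mutant, same half-saturation
for (g in c(control = 400, mutant = 220)) NULL
erg_truth <- list(control = list(r_max = 400, log_ka = -0.5),
                  mutant = list(r_max = 220, log_ka = -0.5))
for (nm in names(erg_truth)) {
  sw <- make_erg_sweep(erg_truth[[nm]], noise_sd = 20,
                       seed = seed + match(nm, names(erg_truth)))
  write_manifest(sw$manifest, file.path(out, paste0("erg_", nm, "_manifest.json")))
  utils::write.csv(data.frame(intensity_cds_m2 = sw$sweep$intensities,
                              amplitude_uV = sw$sweep$amplitudes),
                   file.path(out, paste0("erg_", nm, ".csv")),
                   row.names = FALSE)
}

# one example stained field image (PNG) with its truth
fld <- make_field_image(12, seed = seed)
write_manifest(fld$manifest, file.path(out, "field_manifest.json"))
write_channel_png(fld$image$pixels, file.path(out, "field_example.png"))

# qPCR cohort: heterozygotes at fold 1, homozygotes reduced
qpcr <- make_qpcr_table(c(P23H_het = 1, G188R_het = 1,
                          P23H_hom = 0.3, G188R_hom = 0.3),
                        ct_noise_sd = 0.2, replicates = 3, seed = seed)
write_manifest(qpcr$manifest, file.path(out, "qpcr_manifest.json"))

cat("Synthetic inputs and manifests written to", out, "\n")
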