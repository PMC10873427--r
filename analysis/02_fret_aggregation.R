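#!/usr/bin/env Rscript
# FRET aggregation profiling: efficiencies from donor dequenching, hyperbola
# fits per component, specificity against the non-specific ceiling, and the
# oligomer/aggregate split of the specific signal.

suppressMessages(library(retinaggr))
dir.create("results", showWarnings = FALSE)
seed <- 20240216
ceiling_emax <- 0.05  # non-specific FRET ceiling used for the synthetic study

ds <- make_fret_dataset(0.30, 1.5, 0.10, 1.5, noise_sd = 0.01, seed = seed)
pts <- fret_points(ds$series)

rows <- lapply(c("total", "dm_sensitive", "dm_insensitive"), function(comp) {
  spec <- test_specificity(pts, ceiling_emax, component = comp)
  fit <- spec$fit
  data.frame(component = comp,
             e_max = fit$e_max, se_e_max = fit$se_e_max,
             ec50 = fit$ec50, se_ec50 = fit$se_ec50,
             n = fit$n_points,
             f_statistic = spec$f_statistic, p_value = spec$p_value,
             is_specific = spec$is_specific)
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/fret_fits.csv", row.names = FALSE)

fit_s <- fit_fret_curve(pts, "dm_sensitive")
fit_i <- fit_fret_curve(pts, "dm_insensitive")
fr <- component_fractions(fit_s, fit_i,
                          tab$is_specific[tab$component == "dm_sensitive"],
                          tab$is_specific[tab$component == "dm_insensitive"])

cat("FRET saturation fits (truth: sensitive Emax 0.30, insensitive 0.10):\n")
print(tab, row.names = FALSE)
if (fr$defined) {
  cat(sprintf("Specific FRET split: %.0f%% oligomer (DM-sensitive), %.0f%% aggregate (DM-insensitive)\n",
              100 * fr$fraction_sensitive, 100 * fr$fraction_insensitive))
} else {
  cat("No specific FRET component above the ceiling.\n")
}
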