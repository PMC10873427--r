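#!/usr/bin/env Rscript
# ERG dose-response: fit amplitude-vs-intensity sweeps for a control and a
# degenerating genotype, select standard vs biphasic per sweep, and read off
# the Rmax / KA interpretation.

suppressMessages(library(retinaggr))
dir.create("results", showWarnings = FALSE)
seed <- 20240216

truth <- list(control = list(r_max = 400, log_ka = -0.5),
              mutant = list(r_max = 220, log_ka = -0.5))
rows <- lapply(names(truth), function(nm) {
  sw <- make_erg_sweep(truth[[nm]], noise_sd = 20,
                       seed = seed + match(nm, names(truth)))
  sel <- select_erg_model(sw$sweep)
  fit <- sel$preferred
  data.frame(genotype = nm, wave = "a", regime = "scotopic",
             model = fit$model,
             r_max = fit$r_max, se_r_max = fit$se[["r_max"]],
             log_ka = fit$log_ka, se_log_ka = fit$se[["log_ka"]],
             f_statistic = sel$f_statistic, p_value = sel$p_value)
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/erg_fits.csv", row.names = FALSE)

cat("Dose-response fits (scotopic a-wave):\n")
print(tab, row.names = FALSE, digits = 3)
dr <- tab$r_max[tab$genotype == "control"] - tab$r_max[tab$genotype == "mutant"]
dk <- abs(tab$log_ka[tab$genotype == "control"] - tab$log_ka[tab$genotype == "mutant"])
cat(sprintf("\nRmax reduced by %.0f uV with logKA shift of %.2f:\n", dr, dk))
cat("a reduced Rmax at unchanged KA indicates loss of rods while the\n")
cat("surviving rods keep normal phototransduction sensitivity.\n")
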