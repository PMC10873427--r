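#!/usr/bin/env Rscript
# Expression quantification: comparative-CT qPCR folds for rhodopsin
# transcripts and blot densitometry relative to control.

suppressMessages(library(retinaggr))
dir.create("results", showWarnings = FALSE)
seed <- 20240216

# transcripts: heterozygotes at control level, homozygotes reduced
truth <- c(P23H_het = 1, G188R_het = 1, P23H_hom = 0.3, G188R_hom = 0.3)
tbl <- make_qpcr_table(truth, ct_noise_sd = 0.2, replicates = 3, seed = seed)
qpcr <- do.call(rbind, lapply(names(tbl$samples), function(nm) {
  rq <- ddct_fold(tbl$samples[[nm]], tbl$control, "18s_rrna")
  data.frame(genotype = nm, basis = "ddct", true_fold = truth[[nm]],
             fold = rq$value, delta_delta_ct = rq$delta_delta_ct)
}))

# protein: summed rhodopsin bands over GAPDH, relative to control;
# heterozygous retinas carry about half the control rhodopsin, homozygous
# retinas only a few percent
lanes <- list(control = list(bands = c(80, 20), gapdh = 50),
              het = list(bands = c(40, 10), gapdh = 50),
              hom = list(bands = c(1.6, 0.4), gapdh = 50))
norm <- vapply(lanes, function(l) normalize_lane(l$bands, l$gapdh), numeric(1))
blot <- data.frame(genotype = names(lanes), basis = "densitometry",
                   true_fold = c(1, 0.5, 0.02),
                   fold = relative_to_control(norm, norm[["control"]]),
                   delta_delta_ct = NA_real_)

tab <- rbind(qpcr, blot)
utils::write.csv(tab, "results/expression.csv", row.names = FALSE)
cat("Relative expression (fold vs control):\n")
print(tab, row.names = FALSE, digits = 3)
cat("\nTranscript levels stay near control in heterozygotes while protein\n")
cat("drops to about half, consistent with degradation of the mutant allele's\n")
cat("product rather than a transcriptional effect.\n")
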