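# retinaggr

Quantitative analysis of rhodopsin-mutant aggregation and the retinal
degeneration it drives, for researchers working with misfolding-mutant
models of autosomal dominant retinitis pigmentosa (adRP). The package
implements, as tested reusable functions, the measurement chain that links
in-vitro aggregation of P23H (partial misfolding) and G188R (complete
misfolding) rhodopsin to in-vivo photoreceptor loss in knockin mice — and
pairs every stage with a seeded synthetic-data generator so the whole
pipeline runs with no raw measurements.

## What it computes

**FRET aggregation profiling.** Donor (mTq2) dequenching at 476 nm under
untreated / DM / SDS conditions gives the efficiency decomposition
*E*<sub>total</sub> = (F<sub>SDS</sub> − F<sub>0</sub>)/F<sub>SDS</sub>,
*E*<sub>insens</sub> = (F<sub>SDS</sub> − F<sub>DM</sub>)/F<sub>SDS</sub>,
*E*<sub>sens</sub> = *E*<sub>total</sub> − *E*<sub>insens</sub>:
DM-sensitive FRET reports rhodopsin oligomers, DM-insensitive FRET reports
aggregates. Efficiency versus acceptor:donor ratio is fit to
*E* = *E*<sub>max</sub>·x/(EC<sub>50</sub> + x), and each *E*<sub>max</sub>
is tested against the non-specific FRET ceiling with an
extra-sum-of-squares F test, F = (SS₀ − SS₁)/(SS₁/(n − 2)).

**Colocalization.** Pearson's r between two confocal channels with
replicate mean ± SD summaries.

**ONL decay kinetics.** Nuclei counts spanning the outer nuclear layer,
window-averaged at 600/800/1000 μm from the optic nerve, fit jointly to the
one-phase decay y = (y₀ − plateau)·e<sup>−kx</sup> + plateau with shared y₀
and plateau fixed at 1 (rod loss only); rate-constant comparisons
(ratio, % difference, rounded fold); exponential (one-hit) versus sigmoidal
(cumulative damage) model discrimination by AICc. The published rate
constants for both knockin models ship as `onl_decay_rates()`.

**ERG dose-response.** Standard model
R = R<sub>max</sub>/(1 + 10^(logK<sub>A</sub> − logI)) and its biphasic
two-site extension, fit in log-intensity space with nested F-test model
selection.

**Field particle counting.** Otsu (or manual) thresholding plus
connected-component labeling with a physical-area filter for TUNEL /
PROTEOSTAT / DAPI counts in 317 × 317 μm retinal fields.

**Expression.** Western densitometry (summed rhodopsin bands / GAPDH,
relative to control) and comparative-CT qPCR folds, 2^(−ΔΔCT).

## Worked example

Joint decay fitting at the published superior-retina rates, with the fold
comparison between genotypes (from `analysis/04_onl_kinetics.R`):

```r
library(retinaggr)

ref   <- onl_decay_rates()
keep  <- ref$region == "superior" & ref$genotype != "B6"
rates <- setNames(ref$k[keep], ref$genotype[keep])

ds  <- make_onl_series(rates, noise_sd = 1, seed = 20240216)
fit <- fit_one_phase_decay(ds$series)   # shared y0, plateau fixed at 1
fit$per_series
#> # A tibble: 4 × 3
#>   series        k   se_k
#> 1 P23H_het  0.224 0.0201
#> 2 G188R_het 0.476 0.0419
#> 3 P23H_hom  1.735 0.1440
#> 4 G188R_hom 3.311 0.3668

rate_ratio(0.49, 0.24)$rounded_ratio        # G188R/+ vs P23H/+: 2-fold faster
#> [1] 2
round(rate_ratio(1.84, 1.55)$percent_difference)  # P23H hom, superior vs inferior
#> [1] 19
```

The fitted k track the generating truth (0.24, 0.49, 1.84, 3.29 month⁻¹)
within their standard errors; the fold statements say loss in G188R/+
retina runs twice as fast as in P23H/+, and superior loss in homozygous
P23H runs 19% faster than inferior.

The numbered scripts under `analysis/` walk the full chain on synthetic
inputs (01 simulate → 02 FRET → 03 colocalization → 04 kinetics → 05 ERG →
06 field counts → 07 expression → 08 orchestrated report); each writes its
tables under `results/` and prints what it found. `run_pipeline()` runs the
same stages from one (YAML or list) config with validation, per-stage
failure isolation, and provenance-stamped exports.

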