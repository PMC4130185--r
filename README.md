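# hippoquant

Quantitative analysis of hippocampal synaptic-plasticity experiments in R:

* **Per-cell immunofluorescence** — nuclear-seeded watershed segmentation of
  multichannel confocal micrographs (threshold → soma dilation → Euclidean
  distance map → seeded watershed → per-cell mean marker intensity), for
  studies that score protein expression cell by cell across hippocampal
  subfields (CA1, CA3, dentate gyrus).
* **Calcium transients** — f/f0 normalisation of glutamate-evoked
  responses, peak and area-under-curve quantification, and shape-based
  classification of cells into neurons (sustained plateau) versus
  non-neuronal cells (sharp transient).
* **fEPSP / LTP series** — theta-burst stimulation bookkeeping,
  percent-of-baseline normalisation, early (20–40 min) and late (40–80 min)
  LTP window means, paired-pulse ratio.
* **Statistics** — Kruskal–Wallis with Dunn's Bonferroni-adjusted post hoc
  comparisons, Mann–Whitney U with exact small-sample p values, one-way
  ANOVA with Bonferroni pairwise tests, Pearson correlation / linear
  regression, and Monte-Carlo calibration checks.
* **Synthetic data with ground truth** — generators for micrographs,
  labelled calcium traces and LTP series whose latent parameters are
  returned alongside the data, so every pipeline stage is validated by
  parameter recovery.

The core statistic of the imaging arm is, for each cell *i* with combined
nucleus + soma pixel set *S<sub>i</sub>*, the mean marker intensity
*ȳ<sub>i</sub>* = (1/|S<sub>i</sub>|) Σ<sub>p∈S<sub>i</sub></sub> I(p) on
unit-normalised images (I = raw / (2<sup>12</sup> − 1)). The calcium arm
reports f/f0 (f0 = mean baseline fluorescence per cell), the peak, and
AUC = ∫ (f/f0 − 1) dt; the ephys arm reports window means of
100 · amplitude / baseline-mean. See `vignettes/hippoquant-methods.Rmd` for
the full model description and all conventions.

## Worked example

```r
library(hippoquant)

# --- images: simulate, segment, measure --------------------------------------
sim <- gen_image(image_spec(n_cells = 40, image_shape = c(512, 512)), seed = 1)
seg <- segment_image(sim$image)
nrow(seg$cells)
#> [1] 40
head(seg$cells[, c("cell_id", "nucleus_area", "soma_area",
                   "mean_marker_intensity")], 3)
#>   cell_id nucleus_area soma_area mean_marker_intensity
#> 1       1          241       585             0.7638019
#> 2       2          250       598             0.6828268
#> 3       3          253       602             0.3527056

# --- calcium: control vs 0.5x attenuated treatment ---------------------------
g_ctl <- gen_traces(30, 30, attenuation = 1,   seed = 2)
g_trt <- gen_traces(30, 30, attenuation = 0.5, seed = 3)
auc <- function(g) vapply(lapply(g$traces, trace_features), `[[`,
                          numeric(1), "auc")
group_auc_compare(auc(g_ctl), auc(g_trt))
#> Mann-Whitney U test, normal approximation (tie-corrected, continuity-corrected)
#>   U = 2959, p = 1.198e-09

# --- LTP: window means recover the simulated potentiation --------------------
ltp <- gen_ltp_series(ltp_truth(early_potentiation = 200,
                                late_potentiation = 150), seed = 4)
ft <- percent_of_baseline(ltp$series)
c(early = ft$early_mean, late = ft$late_mean, first10 = ft$first10_mean)
#>    early     late  first10
#> 198.4394 148.8356 198.1413
```

All 40 simulated cells are recovered; the treated group's calcium AUCs sit
far below control (U = 2959 of a possible 3600, p ≈ 10⁻⁹); and the LTP
window means land within the sweep noise of the simulated 200% / 150%
potentiation levels.

A thin command-line wrapper over the same functions is installed at
`inst/cli/hippoquant.R` (subcommands `run`, `simulate`, `segment`, `tbs`,
driven by a YAML config); `run_pipeline()` is the programmatic equivalent
and writes a manifest with config snapshot, checksums and timings beside
its outputs.

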