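---
title: "Methods: per-cell immunofluorescence, calcium and LTP quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell immunofluorescence, calcium and LTP quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippoquant)
```

hippoquant quantifies three kinds of measurements that together describe
hippocampal synaptic plasticity experiments: per-cell marker expression from
multichannel confocal micrographs, glutamate-evoked calcium transients from
live-cell imaging, and fEPSP/LTP time series from acute-slice
electrophysiology, plus the nonparametric statistics used to compare them. A
ground-truthed synthetic-data generator emulates all three inputs so that
every stage can be validated by parameter recovery rather than by eye. This
vignette documents the models, the tunable parameters and their defaults,
the numerical conventions, and what the synthetic validation does and does
not establish.

## Per-cell immunofluorescence quantification

The measurand is the per-cell mean marker intensity: for every cell in a
field, the arithmetic mean of the marker channel over the combined
nucleus-plus-soma region. The segmentation chain is the classical
nuclear-seeded watershed pipeline:

1. **Normalisation.** Raw detector counts are mapped linearly to the unit
   interval by dividing by `2^bit_depth - 1` (12-bit acquisition by
   default). The map is strictly monotone, so thresholds expressed on
   `[0, 1]` are acquisition-independent.
2. **Nuclear thresholding.** Pixels at or above an intensity threshold form
   the nuclear foreground; 8-connected components below a minimum area are
   discarded. The threshold defaults to an Otsu split of the channel
   histogram (256 bins) because an automatic, reproducible default is
   preferable to an undocumented manual one; both the threshold and the
   minimum area (default 30 px²) are explicit parameters.
3. **Soma designation.** The nuclear mask is dilated by a Euclidean disc
   (default radius 5 px) to stand in for the soma surrounding each nucleus.
   Dilation is exact: a pixel is foreground iff its squared distance to some
   mask pixel is at most the squared radius.
4. **Distance map.** Each foreground pixel is assigned its Euclidean
   distance to the nearest background pixel, with the image treated as
   bordered by background. This border convention makes the map independent
   of whatever lies outside the field and keeps the all-foreground case
   well defined.
5. **Watershed separation.** Seeds are local maxima of the distance map
   (8-neighbourhood, plateaus included), greedily thinned so surviving
   seeds are at least `min_distance_px` apart (default 10 px; candidates
   ranked by decreasing height, ties broken by raster order so the output
   is deterministic). The foreground is then flooded from the seeds in
   order of decreasing distance-map height, which splits touching nuclei
   along the valley between their distance peaks. Objects with equivalent
   radius `sqrt(area/pi)` below `min_radius_px` (default 3 px) are dropped
   and labels renumbered consecutively.
6. **Measurement.** Soma labels are grown from the nuclear labels by the
   same flooding restricted to the dilated region, so each soma contains
   its nucleus region-for-region. Mean marker intensity is computed over
   the full soma label (nucleus included, not an annulus) — the literal
   reading of "combined nuclear and surrounding soma expression". No
   background subtraction is applied by default; whether the original
   analyses subtracted background is unknowable from the description, and
   an explicit no-op default is easier to reason about than a hidden
   correction.

The minimum-radius filter is applied to nuclear objects (not to dilated
somata): the nucleus is the detection unit, and filtering detections before
dilation keeps the soma stage purely geometric.

Pearson correlation and ordinary least squares between per-cell channel
intensities (`correlate_channels()`) support scatter analyses relating
marker expression to a reference stain; these are standard model fits
delegated to `lm()`/`cor.test()`.

### Compiled kernels

Connected-component labelling (8-connectivity), exact disc dilation and the
seeded priority-flood watershed are small Rcpp routines: each is a contract
the brute-force test oracles check pixel-for-pixel, and flooding a raster
with a priority queue is not practical in interpreted R at 1024 × 1024
scale. The Euclidean distance transform itself is delegated to EBImage's
`distmap`, wrapped with a one-pixel background pad to impose the border
convention above.

## Calcium transient analysis

Traces are per-cell fluorescence series with an acquisition protocol (frame
rate, baseline duration, stimulus onset/offset, total duration). Two
standard protocols are built in:

* **Organotypic slices** (`organotypic_protocol()`): 2 frames/s, 20 s
  baseline — so f0 averages 40 frames — glutamate at 20 s remaining in the
  chamber for 105 s, a 125 s time-course (250 frames).
* **Dissociated cultures** (`dissociated_protocol()`): 1 frame/s, 20 s
  baseline, 90 s glutamate exposure, 40 s washout, a 150 s time-course.

Frames are timestamped `(index − 1) / frame_rate`; the baseline excludes the
onset frame. The analysis chain:

* **f/f0**: f0 is the mean raw fluorescence over the baseline window; every
  frame is divided by it. The statistic is invariant under multiplicative
  gain but *not* under additive offsets (tested explicitly) — a camera
  pedestal must be removed upstream.
* **AUC**: trapezoidal integral of `f/f0 − 1` over a window, in
  seconds × dimensionless units. Baseline subtraction makes the flat-trace
  AUC exactly zero, an assertable invariant, and makes the statistic linear
  in the response and additive over adjacent windows. The default window is
  the full post-stimulus course; a 60 s post-glutamate window is available
  for exposure-limited comparisons.
* **Peak**: maximum f/f0 over the post-stimulus window, per cell (the
  per-cell-then-aggregate convention; aggregating the group-mean trace
  first would be a different estimator).
* **Classification**: the qualitative neuron / non-neuron distinction —
  sustained plateau versus sharp transient — is operationalised as the
  plateau ratio: mean f/f0 over the final third of the post-stimulus window
  divided by the peak. A cell is a `non_responder` if peak < 1.2, a
  `neuron` if plateau ratio ≥ 0.6, else `non_neuron`. Both thresholds are
  plain configuration reported in the output; the quantitative rule of the
  original prior-work classifier is not public, so this rule is a
  documented stand-in, not a reproduction.

Group comparisons of per-cell AUC use the Mann–Whitney U test below.

## fEPSP / LTP series analysis

The stimulation bookkeeping and series analysis are deliberately simple and
exact:

* **Theta-burst schedule** (`tbs_schedule()`): the default protocol is
  eight trains of eight pulses at 200 Hz with 2 s between train onsets.
  Pulse k of train j falls at `j·2000 + k·5` ms; the train spans 35 ms
  onset-to-last-pulse, consistent with the nominal ~40 ms train duration,
  and the last pulse lands at 14 035 ms. "2 s intervals between trains" is
  read as onset-to-onset spacing; the alternative (offset-to-onset) differs
  only at the 35 ms scale and the choice is recorded in the protocol
  object. The 0.05 Hz baseline test-pulse rate implies one sweep every
  20 s.
* **Percent of baseline**: amplitudes are divided by the baseline-window
  mean (×100). Windows are half-open `[start, end)` minutes with TBS at
  t = 0; the standard summaries are early LTP (20–40 min), late LTP
  (40–80 min) and the first 10 min post-TBS. The baseline-window mean of
  the percent series is 100 exactly, for any series.
* **Paired-pulse ratio**: second/first response amplitude (the direction is
  a convention; only the ratio's constancy across conditions is
  interpreted).

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline is meant to analyse.

**Images** (`gen_image()`): cells are filled discs — nucleus of radius
6–9 px in the nuclear channel, concentric soma disc 5 px larger carrying the
marker intensity — rendered by max-compositing over a flat background
(0.05), with additive Gaussian noise (SD 0.02) clipped to `[0, 1]`. The
default field is 12-bit 1024 × 1024 with 100 cells, on the order of a
confocal field of a hippocampal cell layer. Discs are the simplest geometry
for which an independent per-pixel renderer is exact, which is what makes
pixel-level oracle tests possible. Placement is rejection sampling with a
minimum separation that keeps somata disjoint by default (so per-cell truth
recovery is exact); `gen_touching_pair()` produces the touching/overlapping
configurations that exercise the watershed. The microscopy realities this
deliberately omits: point-spread blur, optical sectioning, photobleaching,
intensity gradients, non-Gaussian photon statistics, and non-circular or
overlapping 3-D nuclei. Passing recovery tests therefore demonstrates the
pipeline's correctness on its own model, not robustness to those real-data
effects; the noise and intensity defaults are calibration choices, since no
noise statistics are published for the original images.

**Calcium traces** (`gen_traces()`): neurons are a smooth rise (4 s) to the
peak, a 10 s hold, then settling (20 s) onto a plateau at
`plateau_fraction × peak`; non-neurons are an alpha-function transient
(τ = 4 s) falling back to their (near-baseline) plateau. Plateau levels are
floored at baseline. Neuron plateau fractions are drawn from 0.85–0.95 and
non-neuron from 0.1–0.3, with peaks 2.2–3.0 and 2.0–2.8 f/f0 respectively —
far enough apart that classification is a property of shape, not of tuned
thresholds. Treatment is a multiplicative attenuation of the peak.
Templates are scaled by a per-cell f0 (80–120 a.u.) before Gaussian noise
(SD 0.05 f/f0) so the f/f0 stage operates on raw units. Not emulated:
oscillations, partial responders, drift, or bleaching.

**LTP series** (`gen_ltp_series()`): baseline sweeps at 100%, then an early
plateau over `[0, 40)` min and a late plateau from 40 min, with an optional
post-tetanic transient `ptp_amplitude·exp(−t/decay_constant)` (default
amplitude 0) and Gaussian sweep noise (SD 3%). The piecewise-constant
profile was chosen over a smooth early-to-late interpolation so that the
standard window means recover the generator parameters *exactly* in the
noiseless limit — making parameter recovery an unambiguous pass/fail
criterion rather than a tolerance negotiation. Defaults (200% early, 150%
late) are in the range reported for disinhibited dentate LTP.

All generators take one explicit seed, use a fixed RNG kind, and restore the
caller's RNG state, so identical calls are bitwise identical and nothing
leaks into global state.

## Statistics

* **Kruskal–Wallis**: tie-corrected H (mid-ranks), chi-square p with
  k − 1 df. All-identical data returns H = 0, p = 1 rather than an error.
* **Dunn's post hoc**: pairwise z from mean ranks with the standard tie
  correction, two-sided normal p, Bonferroni-adjusted over all pairs and
  capped at 1. The adjustment variant is labelled in the output because
  "Dunn's test" alone underdetermines it. Note a structural property of
  rank tests: between adjacent non-overlapping groups the mean-rank
  difference — hence z — is bounded by the group sizes alone (z ≈ 2.54 at
  k = 3, n = 10), no matter how separated the values are.
* **Mann–Whitney U**: U counts first-group-greater pairs (ties ½),
  computed from the rank-sum identity. The p value is exact for
  `n_a·n_b ≤ 400`: from the exact null distribution of U when untied, by
  full labelling enumeration when tied and the enumeration is feasible
  (≤ 2×10⁵ labelings); otherwise the tie-corrected,
  continuity-corrected normal approximation. The method actually used is
  recorded in every result.
* **One-way ANOVA + Bonferroni**: classical F with pooled-SD pairwise t
  tests, delegated to base R's `aov()`/`pairwise.t.test()`; zero-variance
  input returns a flagged degenerate result.
* **Calibration**: `type1_error_sim()` replays each test on all-null
  Gaussian groups; at α = 0.05 and 2000 replicates all three rejection
  rates fall inside the 99% binomial band around 0.05.

Per-cell observations are treated as independent replicates, matching how
cell-level statistics are conventionally reported for this kind of data; no
hierarchical (per-animal) model is fitted, though a per-animal aggregation
can be performed upstream of the tests by averaging records before calling
them. Significance levels are per-analysis configuration; raw and adjusted
p values are both reported so any threshold is reproducible.

## Numerical conventions and edge cases

* Coordinates are `(row, col)` with 1-based matrix indexing at the R level;
  areas in px²; intensities in `[0, 1]`.
* Connectivity is 8-neighbour for components, seeds and flooding.
* Watershed determinism: seed candidates sorted by (−height, row, col);
  flooding breaks equal-height ties by insertion order. Reruns are
  byte-identical.
* Quartiles in box-plot summaries use linear interpolation (R type 7);
  whiskers are Tukey 1.5 IQR, clamped to the data.
* Degenerate inputs have defined behaviour throughout: empty masks, empty
  label maps, all-background distance maps, zero-cell images and flat
  traces all return well-typed empty/neutral results; genuinely
  uninterpretable inputs (non-positive f0, reversed windows, broken label
  containment, infeasible packing) raise errors naming the problem.

## Problem sizes used in the tests

The shipped tests validate on 256 × 256 fields with 25 cells (20 seeded
replicates for the noisy-recovery suite), 200 labelled traces, 100
treatment-comparison replicates at n = 50 cells/group, 2000 calibration
replicates per test, and 200 LTP series — sizes chosen so the full suite
exercises every recovery criterion at tight tolerances while remaining
quick to run routinely. The geometry scales to the default 1024 × 1024
field without any parameter change.

## Known limitations

* The segmentation is 2-D and disc-oriented; elongated or lobed nuclei will
  be split or merged depending on `min_distance_px`.
* The neuron/non-neuron rule is a documented stand-in for a prior
  quantitative classifier that is not public.
* f/f0 assumes an offset-free signal; AUC assumes the baseline is
  representative.
* The synthetic generator's realism limits are listed above; conclusions
  about real micrographs require the usual spot checks against manual
  counts.
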