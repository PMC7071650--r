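# flarequant

Quantitative fluorescence microscopy of membrane lipid reporters (FLAREs) in
budding yeast, as an R package. It is aimed at cell biologists quantifying
polarized lipid distributions and stress-induced protein aggregation: the
kind of study where a PI4P reporter is enriched at the daughter-cell plasma
membrane, redistributes on heat shock, and the regulatory protein involved
aggregates — and where every figure panel rests on a handful of small,
careful image measurements.

The package implements those measurements as tested, reusable functions:

* **PM polarity (Fd/Fm)** — line scans through mother/daughter pairs; the
  two highest reporter peaks coinciding with membrane-marker peaks in each
  cell are averaged (above a local background baseline) and ratioed:
  `ratio = Fd / Fm`.
* **Puncta & ER association** — ImageJ-style noise-tolerant maxima
  (topographic-prominence path criterion), a binary threshold derived from
  the ER marker's specific vs background intensity ranges
  (`thr = bg_max + 0.5 (min_spec − bg_max)`), and the associated fraction.
* **Colocalization** — thresholded pixel-overlap fractions in both
  directions.
* **FRAP** — bias correction by averaged background subtraction, 5×5 ROI
  dilation of bleach templates, incidental-photobleach normalization against
  unbleached regions, and a bounded single-exponential fit
  `F(t) = F∞ − (F∞ − F_post) e^(−k t)` giving mobile fraction
  `(F∞ − F_post)/(1 − F_post)`.
* **Scoring** — percent of cells without cytosolic aggregates over a time
  course; pellet/supernatant fractions `P/(P+S)` from densitometry tables.
* **Statistics** — Welch t and one-way ANOVA wrappers with fixed
  degenerate-input conventions, plus a pipeline orchestrator
  (`run_pipeline()`).

Because raw microscopy for such studies is rarely deposited, a first-class
**synthetic-data module** generates every input the pipeline consumes — cell
pairs with a controllable daughter:mother ratio, ER networks with a
controllable association fraction, FRAP stacks with a controllable mobile
fraction, densitometry tables — with ground truth carried alongside, so every
estimator has a parameter-recovery test. See the methods vignette
(`vignettes/flarequant-methods.Rmd`) for the models, assumptions and
numerical choices.

## Worked example

```r
library(flarequant)

# simulate one budded cell pair: daughter membrane 7.5x brighter
sim <- generate_cell_pair(cell_pair_params(ratio_true = 7.5, snr = 10, seed = 1))
measure_cell_polarity(sim$reporter, sim$marker, sim$geometry)
#> <polarity_measurement> cell: Fd = 15196.8, Fm = 1982.8, Fd/Fm = 7.66

# a 40-cell cohort
simulate_polarity_cohort(40, ratio_true = 7.5, snr = 10, seed = 1)
#> <polarity_cohort> n = 40 (0 flagged): mean Fd/Fm = 7.52 (SD 0.707)
#>   mean Fd = 1.491e+04, mean Fm = 1997

# ER association of 1000 puncta with 80% ground truth
fld <- generate_field(field_params(n_maxima = 1000, assoc_fraction_true = 0.8,
                                   img_size = c(512, 512), seed = 1))
mx  <- find_maxima(fld$puncta, fld$params$puncta_amplitude / 2)
er  <- pm_mask_from_marker(fld$er)
thr <- derive_binary_threshold(fld$er, er, !er)
classify_association(mx, fld$er, thr)
#> <association_result> 800 / 1000 maxima ER-associated (80.0%), threshold 150.5

# FRAP: 22 bleached puncta, true mobile fraction 0.20, 5% noise
sim <- generate_frap_series(frap_sim_params(mobile_fraction_true = 0.2,
         noise_sd = 50, n_bleach = 22, n_reference = 6,
         img_size = c(192, 192), seed = 1))
measure_frap_cohort(sim)$cohort
#> <frap_cohort> 22 traces (0 flagged): mean mobile fraction 0.200 (SD 0.006)
```

The numbers read as: the estimated per-cell polarity ratio and its cohort
mean (recovering the simulated 7.5), the fraction of detected puncta whose
ER-marker intensity at the maximum clears the derived binary threshold
(recovering 80%), and the cohort mean mobile fraction from the exponential
recovery fits (recovering 0.20, i.e. a largely immobile structure).

A thin CLI over the orchestrator lives at `inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --out out demo
```

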