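---
title: "Methods: quantitative microscopy of membrane lipid reporters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative microscopy of membrane lipid reporters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flarequant)
```

# Scope and rationale

`flarequant` implements the quantitative measurements used to study the
distribution of plasma-membrane (PM) phosphoinositide reporters in budding
yeast: daughter/mother PM polarity ratios from line scans, detection of
cortical puncta (PI 4-kinase "PIK patches", stress-induced aggregates) and
their classification as ER-associated, thresholded pixel-overlap
colocalization, FRAP (fluorescence recovery after photobleaching) analysis of
aggregate material state, time-course scoring of aggregation, and
pellet/supernatant fractions from sedimentation densitometry.

Raw microscopy for this kind of study is rarely deposited, so every
measurement stage here is paired with a *synthetic-data generator* whose
ground truth is known exactly. The package's correctness claims are therefore
parameter-recovery claims: when images are simulated at the published
operating points (cohort sizes, signal-to-noise, effect sizes), each
estimator recovers the generator's truth within a stated tolerance. Ground
truth travels alongside the data and is never visible to the measurement
code.

# PM polarity from line scans

## Measurement model

A line is drawn through the daughter and mother cell of a budded pair. Along
the bilinearly interpolated intensity profile, peaks of the PM *marker*
channel (a PH-domain fusion) locate the four membrane crossings; *reporter*
peaks (e.g. a PI4P-binding probe) within ±2 px of a marker peak are
candidates. Within each cell's interval the two highest candidates are
averaged, giving the daughter (Fd) and mother (Fm) membrane intensities; the
polarity ratio is Fd/Fm.

Two details are deliberate choices where manual practice is underspecified:

* **Coincidence window** (default ±2 px): published procedures say reporter
  peaks "coincided" with marker peaks without a tolerance. At 0.1 µm/px, 2 px
  is well under the optical resolution limit, so a true membrane peak cannot
  legitimately fall farther away.
* **Baseline subtraction** (default on): the peak values sit on a cytosolic +
  camera background. We estimate the per-segment background as the median of
  profile samples more than 6 px from every marker peak and subtract it from
  the peak values. Without this, an additive background *b* biases the
  measured ratio toward 1 (for amplitudes $a_d, a_m$ the raw ratio is
  $(a_d+b)/(a_m+b)$, about 4% low at the defaults). With it, the noiseless
  estimator is exact by construction. `baseline = "none"` restores raw peaks.

Cells with fewer than two coincident reporter peaks in a segment are
*flagged*, not silently dropped, so cohort summaries can report analysis
counts the way per-cell figures do. Two invariants pin the estimator down:
rescaling both channels by any positive constant leaves every ratio
unchanged, and swapping the daughter/mother interval labels inverts the ratio
exactly.

## What the generator emulates

`generate_cell_pair()` renders mother and daughter as axis-aligned ellipses
side by side, membranes as Gaussian-profiled rings (σ = half the nominal
membrane thickness), with the two neck-adjacent membranes separated by
`neck_offset` px so the center line crosses exactly four membranes — the
same four-peak profile a manual line scan through a budded pair produces.
The default geometry uses integer crossing coordinates, which makes the
noiseless recovery test exact rather than approximate. Noise is Poisson shot
noise on the expected counts plus additive Gaussian read noise of SD
`base_intensity / snr`, emulating an EMCCD acquisition without modelling EM
gain; `snr = Inf` disables noise entirely and returns the deterministic mean
image.

It does **not** emulate: out-of-focus light, intracellular reporter pools on
organelles, membrane-proximal vesicles, or cell-shape irregularity. Passing
recovery tests therefore demonstrate estimator correctness and noise
robustness, not robustness to segmentation errors or biological confounders;
on real data the line placement and cell intervals remain the analyst's
responsibility (they enter as plain CSV).

```{r polarity-demo}
sim <- generate_cell_pair(cell_pair_params(ratio_true = 7.5, snr = 10,
                                           seed = 1))
measure_cell_polarity(sim$reporter, sim$marker, sim$geometry)
```

At the published operating points (ratios 7.5, 1.5, 5.4, 2.5; cohorts of
40–117 cells at snr 10) the cohort mean recovers truth within a few percent;
the test suite asserts 10%.

# Puncta detection and ER association

## Prominence-based maxima

`find_maxima()` reimplements the noise-tolerant maxima criterion of the
Fiji *Find Maxima* tool: a pixel is a maximum iff no 8-connected path leads
from it to a strictly higher pixel while staying above `value −
noise_tolerance`. Plateaus report one point at the rounded centroid; borders
act as missing neighbours so edge maxima are eligible; a plateau spanning
the whole image (a constant image) reports nothing. The implementation
(plateau grouping + early-exit flood fill) is verified against an exhaustive
brute-force evaluation of the path criterion on hundreds of random small
images — an oracle that shares no code with it.

The default tolerance is 3× a robust noise SD (1.4826·MAD of first
differences /√2); published procedures say only "appropriate noise tolerance
settings", so the default is a documented guess and every analysis records
the tolerance it used.

## The binary ER threshold

Classification of a punctum as ER-associated follows the two-measurement
procedure used with an ER luminal marker: the 1st percentile of marker
intensity *inside* the ER mask defines the minimal specific signal; the 99th
percentile in ER-free regions defines the maximal background; the binary
threshold sits midway between them (`factor = 0.5`, exposed). Percentiles
rather than strict min/max keep single hot or dead pixels from dictating the
threshold. If the two distributions overlap the function refuses to produce
a threshold rather than silently producing a bad one. A maximum whose ER
intensity equals the threshold exactly counts as associated (≥).

`generate_field()` draws a reticulated ER network (random-walk tubules plus
patches, grown to a target coverage), fills on-network pixels uniformly in
`er_intensity_range` and off-network pixels below `background_max`, and
places Gaussian puncta with an exact number of centers on the network:
associated centers are kept ≥1 px inside it and free centers ≥2 px outside,
so a ±1 px localization error cannot flip a truth label. With 1000 spots and
truth fractions 0.80/0.76 the full chain (maxima → threshold derivation from
an unsupervised Otsu ER mask → classification) recovers the truth within 3
binomial standard errors, and in practice exactly.

# FRAP

## Pipeline

1. **Bias correction**: subtract the per-pixel mean of a bias-only
   background stack (default 100 frames; fewer triggers a warning). This
   removes camera offset and any additive illumination gradient.
2. **ROIs**: bleach templates mark single pixels; each is dilated to a 5×5
   square (cropped at borders) before measurement.
3. **Normalization**: each ROI trace is divided by the mean trace of
   never-bleached fluorescent regions (removing incidental whole-field
   photobleaching) and rescaled so its pre-bleach mean is exactly 1:
   $N(t) = \frac{roi(t)/ref(t)}{\mathrm{mean}_{pre}(roi/ref)}$.
   This form makes the pre-bleach-mean-equals-1 contract hold to machine
   precision (normalizing by the two pre-bleach means separately holds it
   only to first order in the noise).
4. **Fit**: $F(t) = F_\infty - (F_\infty - F_{post})e^{-k(t-t_b)}$ by
   bounded Levenberg–Marquardt least squares; mobile fraction
   $(F_\infty - F_{post})/(1 - F_{post})$, immobile fraction its complement.

## Numerical choices

Initialization: $F_{post}$ = first post-bleach value, $F_\infty$ = mean of
the final 3 points, $k = \ln 2 / (T_{post}/2)$; bounds $F_{post}, F_\infty
\in [0, 1.5]$, $k > 0$. Two identifiability rules matter in practice:

* a post-bleach trace that is numerically constant goes straight to the
  model-free endpoint estimator ($F_\infty$ = mean of the last 20% of
  frames), since $k$ is undefined on it;
* if the *fitted* $k$ implies less than one time constant inside the
  post-bleach window ($k\,T_{post} < 1$), $F_\infty$ is extrapolation rather
  than measurement — $(F_\infty, k)$ ride a likelihood ridge and run to the
  bounds — so the endpoint estimator is used instead. Without this rule an
  immobile punctum can be reported as fully mobile.

Fits that fail to converge are flagged and excluded from cohort means;
mobile fractions outside [0, 1] are clipped with a warning. The model-free
endpoint mode is also available outright (`method = "endpoint"`) as a
cross-check; on clean single-exponential data the two agree to ~0.01.

The generator collapses the instrument's multiple rapid bleach cycles into a
single effective bleach depth, renders puncta as flat 5×5 squares (so an ROI
mean has a closed form), applies per-frame exponential incidental bleaching,
a graded camera bias, and Gaussian pixel noise. Cycle-resolved bleaching,
diffusion during the bleach, and z-drift are not modelled; accordingly the
recovery tests validate the estimator chain, not acquisition artifacts.
With 22 ROIs at 5% noise and truth 0.20 (or 8 ROIs at truth 0.33) the cohort
mean lands within ±0.05, the tolerance asserted in the tests.

# Aggregation scoring and sedimentation

A cell is scored "has internal aggregates" iff some maximum lies inside the
cell mask eroded by a cortical band (default 3 px ≈ 0.3 µm) **and** rises at
least the noise tolerance above the cell's median intensity. The amplitude
condition is needed because a diffusely fluorescent cell always contains the
image's global maximum somewhere in its interior; without it every cell
would score positive. This maxima-based rule is a stated re-operationalization
of what is a visual call in practice, with a strict convention: a single
qualifying spot counts as aggregated. Cortical spots never flip the call.

Sedimentation densitometry is plain conservation arithmetic: per lane,
pellet fraction P/(P+S) and supernatant fraction S/(P+S) (summing to 1
exactly), with per-temperature means and SDs over replicates.

# Cohort statistics

`welch_t_test()` (Welch by default — whether published pairwise tests pooled
variances is typically unstated, and Welch is the robust default; Student
via `var_equal = TRUE`) and `anova_oneway()` (classical equal-variance
one-way ANOVA) wrap the standard R implementations behind fixed
degenerate-input conventions (all-constant data gives p = 1). The unit of
analysis is the caller's choice: per-cell for polarity cohorts, per-frame
means for masked-ROI intensity comparisons, matching how such figures report
points. No multiple-testing correction is applied because each comparison is
a single pairwise test. Calibration is verified by simulation: under the
null both tests reject at 5.0% ± 1 point over 10⁴ replicates.

# Problem sizes and defaults

| quantity | default | note |
|---|---|---|
| image size | 256×256 px (fields up to 512×512) | 0.1 µm/px metadata |
| membrane thickness | 3 px (σ = 1.5) | Gaussian ring profile |
| snr | 10 | read noise = base intensity / snr; acquisition SNR and camera bias are not published, so these are exposed placeholders |
| camera bias | 100 counts + 10% gradient | removed by `correct_bias()` |
| coincidence window | 2 px | reporter–marker peak matching |
| noise tolerance | 3 × robust noise SD | maxima detection |
| threshold factor | 0.5 | midpoint between background max and ER min |
| cortical band | 3 px | interior/cortex separation |
| FRAP frames | 10 pre + 50 post, 1 s interval | ≥3 post-bleach required |

Recovery suites use 40–117 cells per polarity cohort, 1000-spot fields,
and 8–22 FRAP ROIs — the cohort sizes the corresponding experiments report —
and complete in about two minutes in total.

# Known limitations

* Geometry is idealized (ellipses, axis-aligned); no automated cell
  segmentation, bud detection, or tracking — cell intervals and line
  placements are inputs.
* The maxima finder is exact for its criterion but single-scale: no
  sub-pixel localization or spot-size estimation.
* FRAP fitting is single-exponential plateau estimation; diffusion-model
  FRAP (Soumpasis/Axelrod) and reaction–diffusion inference are out of
  scope.
* Colocalization is the thresholded overlap fraction only; no
  Manders/Pearson variants.
* The synthetic noise model omits EM-gain excess noise, flat-field structure
  beyond an additive gradient, and photophysics (blinking, triplet states).
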