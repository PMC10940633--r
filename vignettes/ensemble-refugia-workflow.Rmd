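---
title: "Ensemble habitat suitability, climate refugia and fishing risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble habitat suitability, climate refugia and fishing risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep-sea habitat-forming species such as the bamboo coral *Isidella
elongata* — a Vulnerable Marine Ecosystem (VME) indicator, critically
endangered by decades of bottom trawling — occupy narrow environmental
envelopes on the bathyal mud of the continental slope. Two management
questions drive this package: where is habitat suitable today and under a
high-emission future climate (which cells are *climate refugia*, suitable
in both periods), and how much of the observed, suitable and refugial
habitat lies under active trawling pressure.

The package implements the full workflow as reusable, tested functions:
data preparation, two-learner ensemble modelling under repeated
spatial-block cross-validation, uncertainty surfaces, change
classification, and fishing-risk overlay. Because the survey data this
kind of study draws on (trawl-survey occurrence databases, VME records)
are access-restricted, the package ships a synthetic seascape generator
with a *known* suitability truth, so every stage can be exercised and
validated end to end.

## The model

Occurrence is modelled as a Bernoulli response of five predictors —
bathymetry, slope (derived from bathymetry by Horn's eight-neighbour
method), bottom temperature, bottom salinity, and current velocity — with
two learners:

* a binomial GAM with logit link and one thin-plate smooth per predictor,
  basis dimension capped at `k = 4` (at most 3 effective degrees of
  freedom per term), no interactions;
* a probability random forest (500 classification trees by default,
  `mtry` at its default of the square root of the predictor count, no
  depth cap), whose prediction is the per-class vote fraction.

### Spatial-block cross-validation

Occurrence data are strongly spatially autocorrelated, so folds are
assigned at the level of 250-km square tiles laid over the data extent
(kilometres converted at 111.19 km per degree latitude and cos(mean
latitude) for longitude). Occupied tiles are shuffled and dealt
round-robin into five folds — balanced and never empty — and all records
of a tile share its fold. The five-fold CV is repeated 30 times with
fresh random assignments, for 2 x 5 x 30 = 300 model runs. Each run is
fitted on four folds and evaluated on the held-out fold: AUC
(Mann-Whitney form, ties one half), the TSS-optimal threshold, and
sensitivity, specificity, TSS at that threshold. Each run also predicts
present and future probability maps, binarised at the run's own
threshold (the same threshold for both scenarios, so the change
classification reflects environmental change, not threshold drift),
permutation importances (mean AUC loss over shuffles of one predictor at
a time) and partial-dependence response curves.

### Ensemble

Runs in the first quartile of held-out AUC are discarded. The quartile is
operationalised count-wise — exactly `floor(n/4)` lowest-AUC runs
removed, ties broken by run id — because that reproduces the intended
300 -> 225 arithmetic under AUC ties, whereas a strict value rule
(`auc < Q1`) can drop fewer. Failed runs (single-class held-out folds,
possible under spatial blocking) are excluded *before* the quartile is
taken. The ensemble habitat suitability index is the per-cell mean of the
retained runs' *binary* maps — a model-vote fraction in [0, 1] — rather
than a mean of probabilities, so the two algorithms' different
probability calibrations cannot bias the index. The ensemble's own
binarisation threshold is the TSS-optimal threshold of the ensemble
index evaluated at every aggregated record.

### Thresholding conventions

Classification is `prediction >= threshold` (closed on the presence
side) everywhere. The TSS-optimal threshold scans the sorted unique
predicted values plus {0, 1} and returns the *smallest* maximiser: under
ties this favours sensitivity, the right bias when a missed presence
(an undetected VME) is costlier than a false alarm. A floating-point
tolerance of 1e-12 keeps exact TSS ties from being broken by rounding
noise.

## Data preparation

* **Pseudo-absences.** Survey programmes contribute true absences;
  presence-only zones (ROV and literature records) would otherwise bias
  the intercept. In each such zone, pseudo-absences are implanted at
  uniformly random unoccupied cell centres, in number
  `round(presences_in_zone x global survey absence/presence ratio)`,
  never deeper than 1000 m (trawling, hence survey absence information,
  stops there). The global survey ratio is used because a per-zone ratio
  is undefined in zones without survey coverage.
* **Aggregation.** One record per 0.041-degree-class working cell, with
  priority to presences: a single detection suffices to mark a cell's
  conditions suitable, and co-located "noisy absences" are dropped. The
  within-cell choice is uniformly random and seeded.
* **Extraction.** Every predictor is looked up at the record's cell;
  records touching any nodata predictor are dropped and counted.

## The synthetic seascape

The generator emulates the statistical structure of a Mediterranean-scale
study system on a single lon/lat grid (defaults: 100 x 100 cells of
0.15 degrees — a coarser working resolution than a real-data analysis
would use, chosen so that 250-km blocks still tile the extent into
enough folds):

* **Bathymetry**: a north-to-south shelf-to-basin gradient reaching
  about -2600 m, plus Gaussian-filtered correlated noise (kernel sd 4
  cells). Smooth fields are built by convolving white noise with a
  truncated Gaussian kernel, renormalised at the edges; the kernel width
  sets the spatial autocorrelation that makes spatial blocking matter.
* **Temperature**: warm on the shelf, near-isothermal (~13.1-14 degC) at
  depth — the deep Mediterranean is nearly homothermal — plus an
  independent lateral smooth field (sd 0.8 degC) and a 0.6-degC
  west-to-east gradient. Keeping the deep-water temperature variation
  largely independent of depth prevents temperature from being a
  deterministic proxy of bathymetry while preserving their ecological
  correlation on the shelf.
* **Salinity**: 38.4 psu baseline with a smooth field (sd 0.35) and an
  eastward +0.3 gradient, spanning roughly 38-39 psu.
* **Current velocity**: log-normal around a 0.012 m/s median.
* **Future scenario**: identical except temperature + `warming`
  (default 1.5 degC, the mid-range of end-of-century bottom-temperature
  anomalies under a high-emission pathway).
* **Fishing effort**: a log-normal patchy field damped outside the
  200-800 m trawling belt, with the weakest 35% of cells set to zero so
  a no-effort class exists.
* **Regions**: three contiguous longitudinal bands (west/central/east).

The truth surface is logistic in: a Gaussian depth bump (optimum 650 m,
sd 175 m — the species' reported bathymetric ranges span several hundred
metres, so a broad optimum is realistic; amplitude 5 logit units, making
depth the dominant term), a Gaussian salinity bump (optimum 38.8 psu, sd
0.4, amplitude 2), a Gaussian current bump (optimum 0.01 m/s, sd 0.008,
amplitude 1.5), a linear decline of 2 logit units per degC above
14 degC, a weak positive slope effect (0.08 per degree), and intercept
-5.5. With these values the survey prevalence lands near 20%,
comparable to a real trawl-survey dataset, and warming by 1.5 degC
pushes most deep cells past the 14-degC onset, eroding habitat.

Survey stations are sampled uniformly over valid cells shallower than
2000 m outside the presence-only zones; detection is Bernoulli(truth).
Presence-only records are sampled inside two boxes placed in the
optimum-depth band, proportionally to truth.

**What the synthetic data do not emulate**: real coastline and basin
geometry, sampling-effort gradients within the survey, gear-dependent
detectability, temporal trends within the present period, and
observation error in the predictor layers. Passing the recovery tests
therefore shows the *machinery* is correct and that the method recovers
a known signal under realistic spatial dependence — not that any
real-data result is reproduced.

## Uncertainty surfaces

1. **Calibration uncertainty**: per-cell mean of the retained binary
   maps divided by their standard deviation (population form, divisor
   n). This is an inverse coefficient of variation: *high* values mean
   the vote is stable across fold assignments. Cells with sd = 0
   (unanimous models) are set to nodata and counted.
2. **Algorithm disagreement**: the full ensemble methodology applied
   separately to retained GAMs and retained RFs (each sub-ensemble gets
   its own threshold, calibrated on the present-day sub-ensemble), then
   cross-tabulated into both-suitable / both-unsuitable / GAM-only /
   RF-only.
3. **Model-observation comparison**: ordinary kriging of the 0/1 survey
   detections (pseudo-absences excluded; duplicate locations averaged
   first) with a variogram fitted by weighted least squares (Cressie
   weights, spherical model by default) to the empirical semivariogram.
   The 20-km "distance buffer" is read as a prediction mask — no
   prediction further than 20 km from a record — because the
   interpolated occurrence field is only meaningful near surveyed
   corridors. The kriged surface is binarised at 0.5 (an
   indicator-kriging convention, exposed as configuration) and compared
   with the ensemble's binary map inside the surveyed footprint.

## Projection, refugia and fishing risk

Present and future ensemble maps are binarised at the ensemble threshold,
masked to the study area (cells shallower than 2000 m), and
cross-classified into gain / loss / refugia / absence. Loss and gain
percentages are shares of the *currently suitable* area
(loss + refugia), matching the "share of today's habitat lost" reading;
cell-count variants are reported alongside the area-weighted primary
ones. Areas use exact spherical cell areas (R = 6371 km).

Fishing effort is discretised at the quartiles of the positive-effort
cells (zeros form their own no-effort class; the lowest published bin
edge starting just above zero implies zeros were excluded from the
quantiles), with the standard linear-interpolation quantile convention.
Edges are always recomputed from the data. The risk classes are overlaid
on three binary footprints — kriged observed presence, present suitable
habitat, climate refugia — and summed as km2 per region and class, plus
a basin-wide row.

## Numerical choices and degenerate inputs

* Nodata propagates: any operation consuming a nodata cell emits nodata
  (slope at borders and next to nodata cells; predictions where any
  predictor is missing; change classes where either binary is missing).
  A slope is also withheld at a nodata centre cell even though Horn's
  differences do not consume it.
* Horn slope converts degrees to metres per row:
  `dx = cell_size * (pi/180) * R * cos(lat)`, `dy` likewise without the
  cosine, R = 6 371 000 m.
* Resampling: averaging for fine-to-coarse, bilinear from the four
  surrounding source centres for coarse-to-fine; resampling onto the
  identical grid is the identity; a bilinear target touching a nodata
  source centre is nodata.
* Kriging solves the full ordinary-kriging system with one factorisation
  per call; the pipeline subsamples survey records to `krige_max_points`
  (default 1500) beforehand, which bounds the dense solve at a
  negligible loss of detail for a 0/1 field.
* Single-class CV test folds are recorded as failed runs with a reason,
  and excluded before retention.
* Ties in the within-cell aggregation choice, fold dealing and
  pseudo-absence placement are resolved by seeded random streams; each
  stage derives its own stream from the master seed, so stages can be
  re-run in isolation.

## Problem sizes used by the tests and the acceptance script

The package's checks run the methodology at two scales, chosen as the
smallest sizes at which every structural property is exercised: a
compact 60 x 60-cell seascape with ~600 aggregated records for the
300-run bookkeeping of the full 2 x 5 x 30 configuration (with 60-tree
forests — tree count affects cost, not counts), and the default
100 x 100-cell seascape with ~3000 aggregated records and 3 CV repeats
for parameter recovery (depth-response peak, importance ranking,
truth-ensemble contrast). Truth-level warming comparisons use warming
levels of 0.5, 1.5 and 3 degC.

## Known limitations

* The ensemble index has support on multiples of 1/n_retained; with few
  retained runs the ensemble threshold is correspondingly coarse.
* The mean-of-binaries ensemble discards each model's probability
  magnitude; cells near every model's threshold can flip with small
  fold-assignment changes (which the calibration surface makes visible).
* Kriging a 0/1 variable is used as a descriptive interpolation (as in
  indicator kriging); predictions are clamped to the observed value
  range — negative kriging weights can otherwise overshoot it — but no
  further order-relation machinery is applied.
* The spatial blocks are axis-aligned squares in degree space scaled at
  the mean latitude; at basin scale the east-west tile width therefore
  varies slightly with latitude.
* The collinearity report is advisory; no automatic predictor dropping
  is performed.
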