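# evpsubtype

Size-resolved single-particle profiling and classification of
extracellular vesicle and particle (EVP) samples.

## The problem

Bulk assays report one expression level per membrane-protein marker per
sample and wash out the heterogeneity of the EVP population. A
single-particle interferometric imaging measurement instead records
*each* EVP landing on an aptamer-functionalized sensor, with a
diameter for every particle (30–160 nm working range) — so marker
expression and binding kinetics can be resolved by size subpopulation,
and that size-resolved fingerprint can classify the sample's origin.
This package is for analysts working with such single-particle landing
data (or wanting a ground-truthed simulator of it): it implements the
full chain from raw frame stacks to a cross-validated classifier, with
an optimizer for the size partition itself.

## What it computes

* **Detection** — moving-average (n = 10) preprocessing, adjacent-frame
  differentials, optional Wiener deconvolution by the point-spread
  function, robust-SD thresholding with temporal persistence, and the
  3×3 peak-neighbourhood particle intensity.
* **Sizing** — silica-bead calibration: Gaussian peak fits per bead
  size, a fitted log–log power law `I = c·d^b` (b ≈ 3), and inversion
  `d = (I·r/c)^(1/b)` with a Clausius–Mossotti refractive-index
  compensation factor `r` for the lower-contrast EVPs.
* **Kinetics** — per size group, the cumulative binding curve and a
  nonlinear least-squares fit of the Langmuir saturation model
  `N(t) = N_max·(1 − e^(−kt))`, giving the maximum binding number
  `N_max` and the exponential coefficient `k` (1/s).
* **Features** — the sample × (marker × size-group × quantity) matrix:
  expression levels (marker-positive counts over the total-surface
  count) and optionally kinetic parameters, percentile-normalized by
  the 2.5th/97.5th band.
* **Classification** — multiclass LDA with Ledoit–Wolf shrinkage,
  leave-one-out or stratified k-fold cross-validation, probability
  matrix and one-vs-rest ROC AUCs.
* **Partition optimization** — hill climbing with random restarts over
  the 4096 contiguous groupings of the 13 base 10 nm bins, maximizing
  paired cross-validated accuracy, with an exhaustive-search oracle.
* **Synthetic data** — a generator for calibration runs, event tables
  and image stacks with ground truth at every stage, including a
  five-class × five-marker scenario whose class signal is
  size-localized.

## Worked example

```r
library(evpsubtype)

ds <- default_five_class_scenario(seed = 7, replicates = 8, duration = 600)
ds
#> Synthetic EVP dataset: 40 samples, 5 classes, 5 markers, 174677 events

# calibration: 5% intensity noise, five bead sizes
model <- calibrate_from_run(simulate_calibration_run(cv = 0.05, seed = 7))
model
#> Intensity-size calibration: I = 1.029 * d^2.9932  (r = 1.8405)

# kinetics of one run, EVP-S group (30-70 nm)
ev  <- simulate_marker_run(ds$class_specs$tumourA, "PSMA", 900, seed = 7)$events
cv3 <- cumulative_binding_curve(ev, parse_partition("30-70,70-120,120-160"),
                                duration = 900)
fit_exponential(cv3[["30-70"]])
#> Kinetic fit [30-70]: N_max = 166.2, k = 0.00752 1/s (n = 167, rss = 2.57e+03)

# three-subpopulation features and leave-one-out LDA
prof <- sample_profiles(ds, parse_partition("30-70,70-120,120-160"))
fm   <- assemble_features(prof)
cross_validate(fm$x, fm$labels, scheme = "loo")
#> Classification report (leave-one-out): accuracy 100.0%
#> Per-class AUC: healthy=1.000, tumourA=1.000, tumourB=1.000, ...

# bulk vs fixed vs optimized partition, one paired 5-fold CV objective
cmp <- compare_partitions(ds, restarts = 10, seed = 7)
round(cmp$accuracy, 3)
#>      bulk     fixed optimized
#>     0.225     1.000     1.000
cmp$search
#> Partition search: best accuracy 100.0% with
#> 30-60,60-80,80-90,90-140,140-160 (130 evaluations)
```

Reading the numbers: the calibration exponent lands at the cubic
scattering law (2.99); the fitted exponential coefficient 0.0075 1/s is
the association rate of small (30–70 nm) PSMA-positive EVPs in this
simulated class. Bulk analysis scores 22.5% — near the 20% chance level
for five classes, because every tumour class carries the same *overall*
marker levels — while any size-resolved analysis separates all five
classes perfectly, since the classes differ in *where* their
marker-positive EVPs sit in the size distribution.

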