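---
title: "Size-resolved single-particle EVP profiling: models and methods"
author: "evpsubtype authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-resolved single-particle EVP profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evpsubtype)
```

## The measurement and the model

Interferometric plasmonic microscopy images individual nanoparticles as
they land on a sensor surface. When the surface is coated with an
aptamer against a membrane protein (CD63, EpCAM, HER2, PSMA or PTK7),
only extracellular vesicles and particles (EVPs) carrying that marker
are captured; a positively charged surface captures every EVP and
provides the total count. Each landing is detected as a transient spot,
its interferometric intensity is converted to a diameter, and the
accumulating detections form a *binding curve* per size class.

`evpsubtype` implements this chain end to end, plus the downstream
classification machinery, and ships a synthetic-data generator with
ground truth for every stage.

### Binding kinetics

Cumulative capture on an aptamer surface is modelled by the
single-exponential Langmuir saturation form

$$N(t) = N_{\max}\,(1 - e^{-k t}),$$

with $N_{\max}$ the maximum binding number (available capture events)
and $k$ (1/s) the exponential association coefficient. These are the
two kinetic features the classifier can consume. `fit_exponential()`
estimates them by nonlinear least squares on the cumulative curve
(unweighted; cumulative counts are serially correlated, so the fit is a
curve summary rather than a likelihood — an increments-based Poisson
weighting would be the alternative, at no benefit for the smooth,
near-saturated curves used here). Initialization uses the final count
and the initial slope; a multi-start grid over $k \in
[10^{-4}, 10^{-1}]$ backs up the first attempt. Defaults: a 900 s
observation window with 1 s resolution, at least 10 time points and 5
events.

The generator inverts this model with a *site-binding* process: each of
$N_{\max}$ sites captures a particle at an $\mathrm{Exp}(k)$ time, so
the observed count is $\mathrm{Binomial}(N_{\max}, 1-e^{-kT})$ and
landing times are i.i.d. truncated exponentials. The expected
cumulative curve equals the Langmuir form exactly, and — unlike an
unconstrained Poisson stream with the matching intensity — the count
can never exceed $N_{\max}$, which keeps the generator consistent with
the saturation interpretation of the model it feeds.

### Imaging and detection

Raw stacks are averaged over `n = 10` consecutive frames and adjacent
averages are differenced, so a particle that lands (and stays) appears
in exactly `n` consecutive differential frames with amplitude $I/n$.
Detection then works per differential frame: optional Wiener
deconvolution by the point-spread function
($\hat{F} = F\,\bar{H}/(|H|^2 + \varepsilon)$, with $\varepsilon$
defaulting to $10^{-3}\max|H|^2$), local maxima above
`threshold_sigma` (default 5) times a MAD-based robust background SD,
and non-maximum suppression within `min_separation_px`. Candidates are
linked across frames; a landing is accepted only if its site re-exceeds
the threshold in `min_persist = 2` consecutive differentials. Because
successive differentials share no raw frames, background exceedances
are independent between them, so persistence squares the per-pixel
false-positive rate: at 5 SD the expected plain single-frame rate on a
256×256 px frame is about 0.02 per frame (Gaussian tail), and the
persistence requirement drives it far below one event per hundred
frames, while a real landing — present in ten differentials — loses no
recall. The landing frame is recovered exactly as the onset
differential plus `n`, and the particle intensity is the mean of the
3×3 pixels around the peak, measured on the sum of the event's `n`
differential frames (the full step amplitude $I$).

The PSF may be measured (averaging max-aligned single-bead images via
`build_psf()`; 30 images of 100 nm beads is the reference recipe) or
synthetic (`make_airy_psf()`). Deconvolution of a band-limited PSF
cannot restore frequencies beyond its support; round-trip fidelity
holds for smooth spots, not for single-pixel impulses.

### Sizing

Calibration beads of 30, 50, 70, 100 and 160 nm define the
intensity–diameter map. Per size, the intensity histogram
(Freedman–Diaconis bins) is fitted with a Gaussian to find the peak
(`fit_intensity_peak()`, floor of 150 beads, with a moment fallback);
the peaks are regressed in log–log space, $\log I = \log c + b \log
d$. The exponent is *fitted* rather than pinned at the theoretical
cubic value so that instrumental deviations are absorbed; on noiseless
cubic data it lands at 3 to $10^{-6}$.

EVPs scatter less than silica at equal size. The compensation factor is
the Clausius–Mossotti contrast ratio

$$r = \frac{(n_{\mathrm{SiO_2}}^2 - n_m^2)/(n_{\mathrm{SiO_2}}^2 + 2 n_m^2)}
          {(n_{\mathrm{EVP}}^2 - n_m^2)/(n_{\mathrm{EVP}}^2 + 2 n_m^2)},$$

with literature defaults $n_{\mathrm{SiO_2}} = 1.46$,
$n_{\mathrm{EVP}} = 1.40$, $n_m = 1.33$ (giving $r \approx 1.84$); the
factor is exposed as a plain override so a measured value can be
injected. Inversion is $d = (I\,r/c)^{1/b}$ — equal intensity maps to
a larger diameter for the lower-contrast EVP.

### Size partitions and features

The analysable range 30–160 nm is pre-separated into 13 base bins of
10 nm; every candidate partition is a contiguous grouping of these
bins (4096 possibilities). Groups are half-open $[lo, hi)$ with the
last group closed at 160 nm, so boundary diameters belong to the upper
group and 160 nm itself is retained; diameters outside the range are
excluded. The classical three-group partition is EVP-S/M/L =
30–70/70–120/120–160 nm.

Per sample, marker and group, the *expression level* is the
marker-positive count divided by the total-surface count. The default
denominator is the sample's overall total, which makes group
expressions additive (they sum to the bulk level); a flag switches to
group-resolved totals, which instead estimates per-band positivity.
Kinetic quantities ($k$, $N_{\max}$) can be added per group. Feature
columns are normalized by the 2.5th/97.5th percentile band
($x \mapsto (x - p_{2.5})/(p_{97.5} - p_{2.5})$, linear-interpolation
percentiles, no clipping), empty-group cells are imputed (0 for
expression, column median for kinetics), and constant columns are
dropped with a warning. Row z-scores (mean 0, SD 1, $n-1$ denominator)
serve the heatmap export.

### Classification

`fit_lda()` is multiclass LDA with the pooled within-class covariance
shrunk toward a scaled identity with a closed-form Ledoit–Wolf
intensity — necessary because fine partitions push the feature count
(up to 13 groups × 5 markers × 2 quantities) past typical sample
counts. Priors are equal by default, since class sizes in a designed
cohort are artifacts rather than prevalences; prediction ties break
toward the lowest class index. Cross-validation is leave-one-out by
default (deterministic, suited to small cohorts) or seeded stratified
k-fold. Reports contain the overall accuracy, the probability matrix
(row-normalized out-of-fold prediction frequencies per true class; its
class-size-weighted diagonal reproduces the accuracy), and per-class
one-vs-rest AUCs computed as Mann–Whitney concordance (ties 0.5) of
out-of-fold posteriors.

### Partition search

`hill_climb()` performs steepest-ascent local search over the
partition lattice: neighbours of a partition are the single-boundary
toggles (12 moves on the 13-bin grid — the smallest move set whose
graph is connected), moves require strict improvement, ties among
equal-best neighbours prefer fewer groups, and the search restarts
from random partitions (each internal boundary kept with probability
1/2, which samples the 4096 partitions uniformly). The objective —
built by `cv_partition_objective()` — is stratified 5-fold CV accuracy
with one fold assignment fixed across all candidates, so partitions
are compared paired; values are memoized, and `exhaustive_search()`
enumerates all 4096 partitions as the oracle that bounds what hill
climbing can achieve. The search objective uses expression features
only: per-partition kinetic features would require a nonlinear refit
per sample × marker × group for every candidate, and the synthetic
study design places its class signal in expression. Kinetic features
remain available for any fixed-partition analysis. An optimized
partition's CV accuracy is an optimistic estimate of generalization —
the search maximizes exactly that quantity — so held-out evaluation on
samples untouched by the search is the honest follow-up when enough
samples exist.

## The synthetic study design

`default_five_class_scenario()` emulates a five-class, five-marker
cohort (20 replicates per class, 900 s runs) whose discriminative
signal is *size-localized*:

* All diameters follow one truncated lognormal (median 90 nm,
  `sdlog` 0.35, truncated to 30–160 nm) — the unimodal shape typical
  of small-EV nanoparticle-tracking profiles; the exact parameters are
  package defaults, not measured values.
* Marker positivity is piecewise-constant on the base grid.
  `banded_positivity()` fixes the *overall* positive fraction and
  concentrates a chosen share of positives in a size band, so classes
  can differ in where positives sit while sharing identical bulk
  levels.
* The four tumour-like classes all have overall positivity 0.30 on
  every marker; `tumourA` concentrates EpCAM and CD63 below 70 nm
  (75% of positives), and `tumourB/C/D` each concentrate a distinct
  marker pair (HER2+EpCAM, PSMA+PTK7, CD63+HER2) above 120 nm (50% of
  positives — the maximum overall level the 120–160 nm mass supports).
  The healthy class is flat at 0.05.
* Marker association coefficients are fixed per marker
  (0.0028–0.0070 1/s, the printed range for slow and fast surfaces),
  the total surface saturates at 2000 counts with k = 0.01 1/s, and
  every run's $N_{\max}$ is multiplied by an independent lognormal
  batch factor (`sdlog` 0.15).

By construction, a bulk (single-group) analysis can separate healthy
from tumour but not the tumour classes from one another — its expected
accuracy sits near 40% with five balanced classes — while any
partition that resolves the 70 nm and 120 nm boundaries separates all
five classes, reproducing the qualitative bulk → three-group →
optimized accuracy ordering as a large gap. What the passing tests
show is therefore that the chain *recovers planted structure of this
kind*; they say nothing about effect sizes in real plasma, where
marker–size coupling is weaker, size distributions differ per class,
and free-protein background, aggregation and instrument drift (all
outside the generator) matter.

## Numerical choices and degenerate inputs

* Diameter sampling under a positivity profile uses rejection
  sampling with a hard guard against vanishing acceptance.
* Exact boundary diameters follow the half-open convention;
  `assign_group()` returns `NA` out of range rather than erroring.
* `percentile_normalize()` refuses columns with fewer than 3 distinct
  values; `zscore_rows()` refuses zero-SD rows; `expression_level()`
  refuses a zero total.
* The Wiener filter refuses an all-zero PSF; $\varepsilon \to \infty$
  sends the output to zero smoothly.
* LDA falls back to a small ridge on the shrunk covariance in the
  (rare) event the Cholesky factorization still fails; with
  `shrinkage = "none"` a singular pooled scatter is an error.
* All generators are seeded through `withr::with_seed()`, so equal
  seeds give bit-identical outputs without disturbing the caller's RNG
  state.

## Problem sizes used in the shipped checks

Unit tests run on reduced cohorts (2–8 replicates per class, 150–400 s
windows). The end-to-end performance checks use the full default
scenario: kinetic recovery at $N_{\max} = 500$ over 20 seeded runs of
900 s; hill climbing (10 restarts) against the 4096-partition
exhaustive oracle on 20 scenario datasets of 100 samples; detection on
256×256 px stacks of 110 frames with 20 landings at differential-domain
SNR 10. These sizes were chosen so the entire suite completes on a
single CPU while keeping every Monte-Carlo margin comfortable.

## Known limitations

* The detector assumes landings persist; dissociation events (negative
  differentials) are ignored rather than counted.
* The calibration inversion propagates no uncertainty from the peak
  fits into diameters; sizing error enters the pipeline only through
  the simulated noise models.
* The k-space processing assumes a supplied or bead-derived PSF;
  estimating the pupil directly from the data's k-space ring is not
  implemented.
* LDA assumes a shared within-class covariance; strongly class-specific
  covariances would favour quadratic or regularized discriminants.
* The hill-climbing objective's CV folds are reused across thousands of
  candidates; the reported optimum is a selection maximum, not an
  unbiased accuracy estimate.
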