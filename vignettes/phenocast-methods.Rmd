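---
title: "Models and methods in phenocast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in phenocast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

phenocast predicts end-of-season fresh biomass (g/m²) of sorghum breeding
plots from three information streams: time-series UAV remote sensing
(plot-mean hyperspectral reflectance and LiDAR point clouds on a handful of
observation dates), daily weather, and genome-wide marker data summarised
as a genotype-cluster ID. This vignette documents the models, the knobs
that matter, the synthetic trial generator the package ships in place of
undeposited field data, and the numerical choices behind each stage.

## The prediction model

The regressor is a stacked recurrent network. Each observation date `t`
contributes a feature vector `x_t` (hyperspectral indices, integration and
derivative features; LiDAR canopy-height statistics and cover; cumulative
weather sums), which two stacked LSTM cells consume in date order. The
final hidden state is concatenated with a one-hot encoding of the plot's
genotype cluster and mapped by a single fully connected layer to scalar
biomass. Training minimises mean squared error with Adam. The defaults
follow common practice for this model family: learning rate 5e-4, 1000
epochs, mini-batches of 64, two stacked cells. Hidden size (64 by default,
exposed in `rnng_config()`) and mini-batch size are not critical; the
package's property checks use hidden = 32 for speed.

Implementation notes:

* The LSTM forward pass, backpropagation through time and Adam are
  implemented in vectorised base R inside the package and are verified in
  the test suite against numerical finite-difference gradients (agreement
  to ~1e-10). At plot-level problem sizes (hundreds of plots, four time
  steps, tens of features) the matrix products are small and R-level
  execution is fast.
* Features and the biomass target are z-scored with statistics fitted on
  the training split only (per feature, pooled over dates). This is
  mandatory for stable recurrent training given the incommensurate feature
  units.
* A 10% validation split monitors MSE every epoch and the weight snapshot
  with the lowest validation loss is retained, which prevents long runs
  from overfitting small panels.
* Evaluation reports the reference R² (`r2_ref()`),
  `1 − Σ(y−ŷ)² / Σ(y−ȳ)²`, which unlike a squared correlation is negative
  for biased predictors; RMSE in g/m²; and a ranking R² computed on
  per-hybrid mean biomass, the quantity a breeder ranks on. The
  cross-validated protocol (`rnng_cv()`) holds out disjoint thirds of the
  plots and pools the three test folds before computing metrics (the
  alternative — averaging per-fold metrics — differs only in weighting;
  pooling was chosen and is applied consistently).

## Feature extraction

The feature catalog is data (`default_catalog()`, YAML round-trip via
`read_catalog()`/`write_catalog()`): 22 hyperspectral features (ten two-band
vegetation indices, four integration windows covering the visible and NIR,
four first derivatives on the red-edge slope at 705–735 nm, and four
integration windows over the 905–1000 nm detector edge), 19 LiDAR features
(height percentiles 10–100, mean, sd, skewness, MAD, IQR, range,
coefficient of variation, canopy volume, and cover above 1.0/1.5/2.0 m —
thresholds suited to a crop reaching ~2.6 m), and three weather features
(cumulative growing degree days with base 10 °C — the standard base for
sorghum — cumulative precipitation and cumulative solar radiation from
sowing to the observation date).

Numerical rules: band lookups use nearest-wavelength matching on the native
272-band grid; integration uses the trapezoidal rule on the native grid;
derivatives use central finite differences; LiDAR heights are normalized by
the median ground elevation per plot (robust to ground-classification
noise); canopy volume sums cell-maximum heights over a 0.1 m planimetric
grid; cover divides points above the threshold by all points in the
segment. Plots whose LiDAR block is missing on some dates (sparse LiDAR
campaigns are the norm) are imputed by carrying the nearest available
date's block, with every imputed cell flagged in the tensor — this
preserves the number of time steps without inventing growth dynamics;
whether to impute, drop, or substitute is genuinely open and the flag lets
users apply their own policy.

## Feature importance and pruning

For each trial and observation date, the plots × features matrix is
column-standardized (hyperspectral, LiDAR and weather features have
incommensurate units, so correlation-matrix PCA is the defensible choice)
and each feature's importance is the sum over the leading principal
components of |loading| × explained-variance ratio. Five components are
aggregated by default — at plot level they typically explain over 90% of
the variance. Importance is computed per sensor block (hyperspectral and
LiDAR separately), matching how the two catalogs are curated; a joint
analysis is available via `by_source = FALSE`. Weather features are
constant across plots within a date and are never pruning candidates.

A feature is flagged within a trial only if it falls in the bottom-q
fraction (rank-based, ties resolved conservatively) at *every* date —
feature relevance is strongly stage-dependent, so a feature that matters at
any stage is kept. Across trials, a strict majority vote (> half) yields
the redundant set, which `drop_features()` removes. The q knob defaults to
0.25 and recovery of planted redundancy is verified at 0.15/0.25/0.35.

## Genotype clustering

Markers are column-centered but not variance-scaled (biallelic 0/1/2
codings share a scale) and projected onto the first 10 principal
components. k-means (Lloyd, 10 random restarts) is run for k = 1..10; a
warm start from the previous k's solution plus the farthest point
guarantees the WCSS curve is non-increasing. The elbow is formalized as
the k maximizing the perpendicular distance to the chord joining the
curve's endpoints, after scaling both axes to [0, 1]; ties break toward
smaller k, and a straight curve returns the smallest k with a `no_elbow`
flag. Cluster IDs are canonicalized (decreasing size, then centroid norm,
then smallest member index) so two runs reaching the same partition emit
identical labels.

## Transfer learning

The source domain is a small calibration panel that can be destructively
sampled; the target is the large testcross panel. Two selection strategies
pick the few target plots worth harvesting for fine-tuning:

* **genomic** — all non-test target plots whose hybrid also appears in the
  calibration panel;
* **phenotype** — k-means on the pool's z-scored flattened feature tensor
  (k by the same elbow rule), taking the `n_per_cluster` plots nearest
  (Euclidean) to each center. The per-cluster count defaults to
  `ceiling(budget / k)` with the budget set to the calibration panel's
  hybrid count, giving selections of comparable size to the genomic
  strategy from the phenotypic side.

Fine-tuning continues Adam from the pre-trained weights on the selected
plots only, with all layers trainable at a reduced learning rate (1e-4,
300 epochs by default) and a fresh 10% validation split of the selection.
Normalization statistics are refit on the selection: the target domain is
shifted in feature space and reusing source statistics would bake the
shift into every input. (The alternative — keeping source statistics —
is a one-line change via `fine_tune()`'s internals but was not adopted.)
`run_transfer_experiment()` evaluates the source-only model, both
fine-tuned models and a target-trained ceiling model on one shared
held-out target test third and reports sample/hybrid counts per model.

## The synthetic trial generator

No field campaign is bundled; `simulate_trial()` generates panels with the
statistical structure the framework assumes, and every downstream claim in
the test suite is made against this generator's hidden truth.

* **Growth.** Each hybrid has a logistic canopy-growth curve (potential
  height ~2.6 m, rate and midpoint mildly hybrid-specific). Plot-level
  replicate variation scales with the biomass-noise knob, so a zero-noise
  configuration makes replicates exactly identical.
* **Markers.** A Balding–Nichols island model: ancestral allele
  frequencies, per-subpopulation drift at Fst 0.3 (strong structure of the
  kind breeding heterotic groups show), binomial genotypes; five
  subpopulations by default.
* **Biomass.** `400 + 1400 × (season-mean canopy height) + subpopulation
  effect + environment effect + G×E + noise`, clipped positive. The
  subpopulation effect (±400 g/m² across clusters) is deliberately *not*
  expressed in the canopy signal — it emulates, e.g., photoperiod-driven
  late accumulation — which is exactly why a genotype-blind model
  under-predicts the top-yielding plots and a cluster-aware model does
  not.
* **Spectra.** A two-endmember soil/vegetation linear mixing model with
  latent factors for chlorophyll (green bump and red trough), red-edge
  position, NIR plateau amplitude, soil brightness and a xanthophyll-like
  wiggle at 531 nm, plus band-correlated smooth noise. Factor amplitudes
  vary by date: the physiological drivers of canopy reflectance differ
  across growth stages, so the dominant features change over the season.
* **Point clouds.** Ground points near z = 0 plus canopy heights on a
  deterministic beta-quantile grid scaled by current canopy height, with
  per-plot-date shape latents (top-heaviness, spread, point fraction)
  whose amplitudes scale with the structural-noise knob — a zero-noise
  cloud is fully deterministic, which the growth-monotonicity invariant
  uses.
* **Planted redundancy.** Four reserved NIR detector-edge windows
  (905–1000 nm) carry a flat plateau plus a per-campaign (per-date)
  calibration drift shared within each window pair. Pooled over dates the
  pair members are near-duplicates (correlation > 0.95); within a date
  they are independent low-amplitude noise with no canopy signal, so the
  per-date importance analysis ranks them decisively lowest. This mirrors
  real VNIR sensor behaviour at the spectral edges and is the mechanism by
  which "redundant" features exist to be found.
* **Domain shift.** The target trial applies an affine shift to
  reflectance and canopy heights (calibration/illumination change between
  fields or years) and an affine shift to biomass (+20%, +150 g/m²) —
  one parameterization spanning both same-year/different-field and
  different-year regimes.
* **Determinism.** All randomness flows from one seed through named
  substreams (`markers`, `weather`, `hybrids`, one per trial), so any
  component can be re-simulated independently and full runs are
  byte-identical under a repeated seed.

What the generator does **not** emulate: radiative-transfer realism,
georeferencing and mosaicking artifacts, within-plot spatial variability
(a plot is one homogeneous unit per date), row geometry beyond a two-row
segment, and moisture/dry-weight partitioning. Passing tests therefore
demonstrate that the pipeline's logic recovers known structure under the
stated assumptions — not that the model attains any particular accuracy on
real fields.

## Problem sizes used by the tests

The property suite runs at desk scale, chosen once as the smallest sizes
at which the studied effects are comfortably resolved: redundancy recovery
uses 6 trials of 300 hybrids × 2 replicates; cluster recovery the full
630 × 2000 panel; the genotype-effect comparison 100 hybrids × 2
replicates with 100 training epochs; the transfer comparison 150 target
hybrids (20 calibration hybrids × 3 replicates as source) with 250 epochs
for training and fine-tuning; the demo pipeline 60 hybrids end to end.

## Known limitations

* The importance analysis is purely linear (PCA loadings); features whose
  relevance is nonlinear can be mis-ranked. Alternative schemes
  (permutation importance) are out of scope.
* In-season prediction from partial sequences is not supported: the model
  consumes the full set of observation dates it was trained on.
* The fine-tuning schedule (all layers trainable at a reduced rate) is a
  default, not a tuned choice; a freeze-recurrent-cells mode would be a
  natural extension.
* k-means seeding uses random restarts rather than k-means++; with ten
  restarts plus the warm start this is robust at the panel sizes involved,
  but pathological marker geometries could require more restarts.
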