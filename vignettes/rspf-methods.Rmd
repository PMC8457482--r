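---
title: "Modelling wildlife-conflict risk with use-availability RSPFs"
author: "rspfrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling wildlife-conflict risk with use-availability RSPFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rspfrisk)
```

## The problem and the model

Wildlife agencies receive reports of human-wildlife conflicts — for black
bears, typically garbage break-ins, residential damage, or livestock
injury — as point locations with a complaint type and a severity class
(1 most severe to 4 least). The question this package addresses is where
such conflicts are likely: given reported conflict locations and a stack
of environmental and anthropogenic raster covariates (elevation, land
cover, population density, road density, distances to roads, streams,
forests, urban and recreational areas, forest density), estimate the
probability that a landscape unit experiences a conflict, and project
that probability into a risk map.

The statistical core is a resource selection probability function (RSPF)
with a logistic link,

$$ w(x) \;=\; \frac{\exp(\beta_0 + \beta_1 x_1 + \dots + \beta_n x_n)}
                   {1 + \exp(\beta_0 + \beta_1 x_1 + \dots + \beta_n x_n)}, $$

where $w(x)$ is the absolute probability of conflict at a location with
covariates $x$. Because true absences are not observed, the design is
use-availability: observed conflicts ("used" points, label 1) are
contrasted against random background locations ("available", label 0)
drawn from the landscape. Estimation maximizes the weighted-distributions
use-availability log-likelihood

$$ \ell(\beta) \;=\; \sum_{i \in \text{used}} \Big[ \log w(x_i;\beta)
     \;-\; \log \tfrac{1}{n_a} \sum_{j \in \text{avail}} w(x_j;\beta) \Big], $$

in which the availability sample stands in for the landscape-wide
covariate distribution. At $\beta = 0$ every $w$ equals $1/2$ and
$\ell = 0$ exactly; the value is invariant to duplicating the
availability sample. Standard errors come from a nonparametric bootstrap
that resamples the used and available strata independently with
replacement, preserving stratum sizes — the unmatched design (`m = 0`);
p-values are two-sided Wald tests on the bootstrap SEs. Whether the
original analysis framework used Wald or percentile p-values is not
documented; Wald-with-bootstrap-SE is implemented and stated in the
output.

## Point preparation

Conflict records are first filtered against a region mask (obviously
erroneous locations dropped, with a count), then spatially thinned so no
two retained points are closer than a minimum distance (default 5 km,
the scale of a ~25 km² bear home range). The thinning algorithm is
randomized greedy elimination: repeatedly delete a uniformly random
point among those with the most neighbours closer than the minimum
distance, until none remain; the procedure is repeated (default 100
runs) and the run retaining the most points wins, ties to the earliest
run. Against exhaustive maximum-independent-set enumeration on small
instances the greedy scheme attains the optimum in well over 90% of
cases; it is near-optimal, not guaranteed.

Background points are drawn uniformly over the region mask minus exact
Euclidean discs of the buffer radius (default 5 km) around every used
point, by rejection sampling with a hard proposal cap (default $10^6$).
Discs are evaluated per candidate point rather than rasterized, so the
exclusion has no resolution artifacts. The background-to-used ratio is
exactly 5, honouring the arithmetic of the study design (683 conflicts
× 5 = 3,415 background points).

## Raster engineering

Rasters are matrix-backed planar grids in metres (`grid_raster`), with
row 1 at the top and half-open cell membership so edge points resolve
deterministically; aligned collections form a `raster_stack`. The
operations mirror standard GIS steps: exact Euclidean
distance-to-feature transforms (two-pass lower-envelope algorithm,
linear time, equal to brute force), categorical reclassification through
an explicit total code map (e.g. sixteen land-cover codes collapsed to
eight classes), natural-log transforms with a configurable offset
(default +1, because distance-to-forest and population density are zero
on parts of their support and the original handling is unstated),
nearest-neighbour resampling onto a target grid (categorical codes never
interpolated), cropping/alignment to a shared extent, and point-value
extraction by cell containment with nodata-flagged points dropped and
counted. Aspect, a circular quantity in degrees, is carried as plain
continuous — matching the source analysis, with the caveat that 0° and
360° are identical directions. I/O uses plain-text formats: ESRI ASCII
grids for rasters, CSV and GeoJSON for point tables. Reprojection
between real-world coordinate reference systems is out of scope; the
analysis core is projection-agnostic.

## Screening and model selection

Collinearity screening has two stages: variance inflation factors
(VIF$_j = 1/(1-R_j^2)$ from the inverse correlation matrix), iteratively
removing the worst offender above 10; then pairwise squared Pearson
correlations above 0.7, dropping the lower-priority member of each pair,
largest $r^2$ first. The priority ordering encodes which covariates are
judged more biologically relevant and is a required user input, not
inferred. Reading "$R^2$ coefficient" as squared correlation is a
choice; thresholding $|r|$ instead is available by argument.

Model selection enumerates all $2^n$ subsets of the screened terms
(including intercept-only; refusing $n > 20$), fits each by maximum
likelihood with the bootstrap disabled (the AIC needs only the MLE — a
pure-runtime decision with identical selection output), and ranks by
AIC $= -2\ell + 2k$. The land-cover term is atomic: all of its
indicator columns enter or leave together, and its reference class is
the most frequent class in the availability sample (recorded in the
output, since coefficients depend on it). The parsimony rule follows the
conventional reading of "comparable AICs": among models within
$\Delta\mathrm{AIC} \le 2$ of the best, the fewest terms wins; ties go
to the lower AIC, then lexicographic term order.

## Validation and mapping

Predictive power is assessed by the rank-based (Mann-Whitney) AUC, an
equal-sensitivity-specificity threshold chosen by scanning the distinct
observed scores plus midpoints (ties to the lowest threshold), and
omission errors: the fraction of used points scoring below the
threshold and of available points scoring at or above it. "Overall"
omission is reported both as the pooled misclassified fraction and as
the mean of the two class rates, because the two conventions give
different numbers and published tables are not always explicit about
which was used. Thresholds are always derived on training data and
applied to test data; deriving them on test data would leak. Two split
designs are provided: a spatial hold-out (train outside a focal
subregion, test inside — the design that asks whether a statewide model
transfers into a focal region) and stratified k-fold cross-validation
(default $k = 5$), each fold serving exactly once as the test set.
Robustness gates (AUC > 0.7, overall omission < 0.3) are evaluated and
reported, not enforced.

The selected model, refitted on all data with the full bootstrap, is
projected cell-wise across the covariate stack into a probability
surface; nodata propagates wherever any required covariate is missing,
unseen category codes are an error, and the computation streams in row
blocks whose size never changes the result. The surface can be cropped
to a focal region and discretized into ordered risk classes with
half-open bins $[a, b)$ — a value exactly at a break goes up a class.

## The synthetic-landscape generator

Because the conflict records behind the motivating analysis are not
public, every stage is exercised against synthetic landscapes with known
truth. Continuous covariate fields are Gaussian white noise smoothed by
a square moving-average kernel of a per-covariate range (in cells), then
rescaled to a stated mean and SD — the simplest construction with
controllable spatial autocorrelation. The categorical cover layer
thresholds an independent smoothed latent field at quantile breaks
(octiles by default give eight spatially coherent classes). Used points
are drawn by rejection: propose a uniform cell in the region mask and a
uniform position within it, accept with probability $w(x)$ — so $w$ is
used exactly as an absolute probability, not a relative weight. The
generator reports its empirical acceptance rate alongside the analytic
spatial mean of $w$ (full-grid summation), and the empirical
cell-occupancy distribution of large draws converges to
$w/\sum w$. A contiguous corner block of the region serves as the focal
submask for spatial hold-out experiments.

A design-level counterpart, `simulate_ua_design()`, skips the raster
machinery for studies of the estimator itself: one finite pool of
locations with standard-normal covariates stands in for the landscape,
used points are accepted from the pool by $w$, and the availability
sample is drawn from the same pool. Sharing one pool matters: if the two
strata came from disjoint unbounded samples, a halfspace could separate
every used point from part of the availability tail, and the likelihood
supremum would sit at infinity — an artifact that raster extraction,
where both strata share the same finite cells, does not have.

What the generator does not emulate: real terrain structure, real
land-cover class proportions, observation and reporting biases in
complaint data, and temporal structure. Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
assumptions, not fidelity to any particular real landscape.

## Numerical choices

* **Optimization.** The likelihood is maximized by L-BFGS-B from an
  ordinary logistic-regression warm start, on internally standardized
  covariates (the optimum is reparametrized exactly back to the raw
  scale — reported coefficients are raw-scale, e.g. an elevation slope
  in probability units per metre). Convergence requires the optimizer's
  own criterion (relative improvement below ~$10^{-11}$) or a gradient
  infinity-norm below $10^{-6}$ on the standardized scale, with one
  restart; non-convergence is a warning, never silent.
* **Compact parameter space.** The search is confined to a box on the
  standardized scale: slopes within ±15 per covariate SD, intercept
  within ±30. Selection odds beyond $e^{15}$ per SD are not
  scientifically meaningful, and compactness is the standard regularity
  condition for this likelihood, whose supremum otherwise escapes to
  infinity under quasi-separation. A slope pinned to a box face is
  reported as separation (an error naming the column); an intercept
  pinned to its face — the weakly identified exponential-tail ridge of
  the logistic RSPF — sets a `ridge` flag on the fit, as does
  near-singular curvature at an interior optimum.
* **Bootstrap.** Refits are warm-started at the full-data estimate with
  a 200-iteration cap; refits that fail to converge or hit a slope face
  are dropped and counted, and more than 5% drops is an error.
* **Ties and boundaries.** Cell membership is half-open (edge points to
  the lower index); hotspot bins are half-open with boundary values
  going up; threshold ties go to the lowest candidate; thinning ties are
  broken uniformly at random within a run and across runs by the
  earliest run index.

## Problem sizes used by the test-suite experiments

The packaged experiments run at desk scale, chosen to make the
statistical properties measurable: parameter recovery uses 50 replicate
48×48 landscapes with 700 used points, a 5:1 availability ratio and 200
bootstrap replicates, checking each true continuous slope against ±2
bootstrap SEs per coefficient; selection consistency uses 25 replicates
of an eight-covariate design (three informative, five noise) with 1,000
used points at 5:1 over a 200,000-location pool; null-data behaviour
uses 50 replicate 32×32 landscapes with constant $w$. The end-to-end
pipeline demonstration uses a 40×40 landscape with 120 conflicts, a
rare-event intercept ($\beta_0 = -4$) and three informative covariates.

Two statistical facts about these experiments are worth knowing. First,
with a finite availability sample the likelihood-ratio statistic for a
pure-noise covariate is overdispersed relative to $\chi^2_1$ by roughly
$(1 + n_u/n_a)$ — at 5:1, noise covariates clear a 2-unit AIC bar in
about 6% of cases rather than 4.6%, so exhaustive selection recovers the
exact generating set in roughly 70–80% of replicates under these
conditions. Second, under null signal the logistic-RSPF intercept is not
identifiable (any constant $w$ fits equally well), and a minority of
null replicates quasi-separate; those end at the box face and are
reported as separation rather than as coefficient estimates.

## A worked example

```{r example, eval = FALSE}
library(rspfrisk)

cfg <- default_config(seed = 11)
res <- run_pipeline(cfg, out_dir = "pipeline-out")

res                       # selected model, AIC, hold-out and k-fold AUC
res$fit                   # coefficient table with bootstrap SEs
res$validation$kfold      # per-fold AIC / AUC / omission errors
res$risk                  # conflict-probability raster
```

The manifest (`res$manifest`) records the config snapshot, per-stage
seeds and md5 checksums of every file written; re-running the same
config is bit-identical.

## Known limitations

* The intercept of a logistic RSPF is weakly identified whenever fitted
  probabilities stay far from 1; intercept-dependent quantities (the
  absolute scale of $w$) should be interpreted with the `ridge` flag in
  mind. Rankings, AUC and omission errors are unaffected, being
  invariant to monotone transforms of $w$.
* The bootstrap treats points as independent; under strong residual
  spatial autocorrelation (the reason the study design thins points)
  its SEs are mildly anticonservative.
* Only the unmatched design (`m = 0`) is supported; no matched-pairs
  designs, no exponential-link RSF, no spatial random effects, no model
  averaging, AICc or BIC.
* Geodesy is out of scope: coordinates are planar metres, and real-CRS
  reprojection must happen upstream.
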