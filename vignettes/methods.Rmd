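---
title: "Predicting post-release movement with circuit theory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting post-release movement with circuit theory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(releaseflow)
```

## The problem

When a critically endangered soaring bird such as the California condor is
reintroduced to part of its former range, managers need to anticipate where
the released animals will go. releaseflow models the landscape as an
electrical circuit: a conductance surface (how easily a bird in flight moves
through each 1-km cell) becomes a lattice of resistors, current is injected
at the release site, drained at a ring of ground nodes encircling the
modelling region, and the resulting per-cell current — averaged over all
source–ground pairs — is read as the net probability of movement through
that cell. The pipeline has five stages: telemetry filtering, conductance
modelling, circuit solving, calibration, and linkage mapping, plus a
synthetic-data generator that makes the whole chain reproducible and
testable without field data.

## Telemetry filtering

Raw GPS tables carry records the analysis must not see. The filters, with
their defaults:

* **fix quality** — only `proofed == 1` records are kept;
* **flight window** — ground speed strictly between 2.78 and 30.0 m/s
  (m/s; both bounds strict, so a fix at exactly 2.78 m/s is dropped); slower
  fixes are perched or walking birds, faster ones are errors;
* **offshore** — points on ocean cells of the land/ocean mask are removed
  (the mask's provenance and resolution are the caller's choice);
* **release-site exclusion** — points within 5 km of any release site (or
  flight-pen/trap site, passed as just another site row) are removed, since
  baiting and captive birds inflate movement frequency there;
* **daily thinning** — one record per bird per calendar day, chosen
  uniformly at random under a fixed seed, to reduce temporal
  autocorrelation. The calendar day is evaluated in a configurable timezone
  (UTC by default; the choice only matters for birds tracked across
  midnight in local time).

Background (availability) data are 10,000 uniform points inside the convex
hull of the movement points buffered by 10 km, clipped to land and excluding
the same 5-km site disks. Sampling is by rejection over the buffered hull's
bounding box — exact, simple, and reproducible under the configuration seed.

## The conductance model

Conductance is the logistic output of a maximum-entropy presence-background
model, reimplemented here as the model class rather than wrapped from the
reference binary. For covariates $z_1 \dots z_k$ the model uses linear and
quadratic features only, each scaled to $[0,1]$ over the background sample.
The fitted distribution over background cells is the Gibbs distribution

$$q_\lambda(i) \propto \exp\!\Big(\sum_f \lambda_f f_f(i)\Big),$$

and the fitter maximises the regularised gain
$\tfrac1m\sum_{\text{presence}}\lambda\!\cdot\!f - \log \mathbb{E}_{\text{bg}} e^{\lambda\cdot f} - \sum_f \beta_f |\lambda_f|$
by cyclic coordinate descent with soft-thresholded proximal Newton steps and
backtracking, capped at 5,000 single-feature updates. The regularisation
follows the published linear/quadratic defaults keyed to presence sample
size $m$ (multipliers 0.65/0.50/0.25/0.05 interpolated at $m$ = 10/17/30/100),
with $\beta_f$ scaled by the presence-sample standard deviation of the
feature over $\sqrt m$. Duplicate presences are retained. Each accepted
update's gain increment is attributed to the feature touched; summed per
covariate and normalised to 100 these give the percent-contribution table.

Projection clamps features to their training range, so predictions outside
the sampled environmental space equal boundary predictions, and applies the
entropy-calibrated logistic transform $c\,q/(1+c\,q)$ with $c=e^{H}$, $H$
the entropy of the fitted background distribution; a cell of typical
suitability scores near 0.5.

Model choice mirrors the published protocol: pairwise Spearman screening at
$|r_s| > 0.70$ (the lower-priority covariate of an offending pair is
dropped; a covariate constant at the points has undefined correlations and
is reported and retained), then 5-fold cross-validation of nested candidate
covariate sets, scored by regularised training gain, rank-based (Mann–
Whitney) test AUC, and AIC with $K$ = the count of non-zero lambdas and the
log-likelihood the sum of log raw probabilities of all presences under the
renormalised model (the convention of the ENMTools ecosystem, since no AIC
formula is fixed for this model class); the candidate with the lowest mean
AIC wins, ties broken toward fewer covariates. The per-fold gain baseline is
the uniform distribution over the background (gain 0 at $\lambda = 0$),
which is the convention reported here.

Derived covariates use their field-standard definitions: Horn's 3×3
finite-difference slope in degrees (edge cells reuse nearest interior
values); terrain ruggedness as the ratio of 3-D to planar surface area,
per-cell areas from a triangle fan between the cell centre and its 8
neighbours, summed over a circular 10-km focal window (so an inclined plane
scores exactly $1/\cos\theta$); and focal mean/median/density statistics
over circular windows that shrink at the grid edge and never wrap.

## The circuit

The conductance raster becomes a graph with one node per cell and
8-neighbour edges weighted by the mean of the two cell conductances, divided
by $\sqrt2$ on diagonals (the average-conductance lattice convention).
Because ground nodes sit outside the modelled study area, conductance is
first filled: ocean cells take the in-study minimum (large soaring birds
avoid open water), outside terrestrial cells the in-study median — a
constant conductive medium, not a movement prediction.

Ground nodes are placed every 10 km along the boundary of the union of
350-km disks around the release sites, computed exactly as circle arcs
clipped against the other disks and walked counter-clockwise from the
easternmost point; the node count is $\lceil P/s\rceil$ for perimeter $P$
and spacing $s$, giving 220 for a single site. One Kirchhoff system is
solved per (source, ground) pair — the grounded graph Laplacian by sparse
Cholesky factorisation, which at these problem sizes (far below $10^5$
nodes) is both exact to machine precision and faster than iterating; the
dense-oracle tests pin the solution error near $10^{-15}$. Per-cell current
is half the sum of absolute incident edge currents (so a pass-through cell
in a series chain reports the through-current), with source and ground cells
reporting the full injection. The unweighted mean over all pairs, times
1,000, is the direction-neutral mean current map in mA. Ground ties are
direct by default; a per-ground resistance is available for
attractant-strength extensions. The post-hoc attractant workflow — pairwise
solves from the source to named high-use destinations, averaged, then
overlaid with the ring map by cellwise maximum — mirrors the published
analysis.

## Calibration

Current maps are evaluated against movement points within 300 km of the
release sites (beyond that, proximity to ground nodes biases current). The
continuous Boyce index compares the "predicted" distribution (current at
movement points) with the "expected" one (current over the evaluation area)
in moving windows — 101 centres, width one tenth of the scale range — and
reports the Spearman correlation between window position and the
predicted/expected ratio.

Two numerical choices matter here. First, windows are placed on the
*quantile* scale of the map distribution by default: mean current maps have
a long upper tail (the source cell carries the full injected ampere), and
value-scale windows there hold a handful of cells each, so sampling zeros
drag the index negative even for a well-calibrated map; quantile windows
equalise the expected mass per window, remove that bias, and make the index
invariant under any strictly monotone rescaling of the map. Window centres
are mapped back to mA for P/E plotting. Second, the expected distribution
excludes the release-site exclusion disks (as well as ocean): movement
points cannot occur there by construction — the same reason the background
sample excludes them — so retaining their extreme currents would compare
observed use against cells where use is impossible. A constant map yields an
undefined index (reported `NA` with a diagnostic), never a silent zero.

The attenuation of movement with current is summarised by the reverse
cumulative frequency of current values at movement points in 1-mA bins: the
fraction of points at or above each threshold, starting at exactly 1 and
non-increasing.

## Linkage networks

Resistance is the reciprocal of conductance ($1/C$; conductance must be
positive — mask or floor zero cells upstream). Core patches come from
binarising a nesting-suitability raster at 0.04 and keeping 8-connected
components of at least 10 km². Cost-weighted distance (CWD) from a patch is
a multi-source Dijkstra (all patch cells at cost 0) with move cost the mean
of the two cells' resistances times the centre distance in km (×$\sqrt2$
diagonal), implemented in compiled code with a predecessor grid. Candidate
links come from cost-weighted network adjacency: every cell is allocated to
its CWD-nearest patch, and patch pairs whose allocation zones share a
boundary are candidates — distant pairs separated by an intervening patch's
zone are excluded. The least-cost path for a pair threads the cell
minimising $\mathrm{CWD}_A + \mathrm{CWD}_B$, recovered from the two
predecessor grids; link endpoints are the cheapest entry cells, ties broken
by lowest cell index for determinism. A link whose interior cells lie inside
a third patch is dropped ("corridors that intersect core areas"), and the
network summary reports the count and mean CWD of the kept links.

## The synthetic generator, and what passing tests do and do not show

The generator emulates the statistical regime the analysis assumes, not
condor biology. Covariate fields are Gaussian-kernel-smoothed white noise —
kernel sd of half the `autocorr_range`, so field autocorrelation falls to
about $e^{-1}$ at that range — standardised to zero mean and unit variance;
a DEM is the same kind of field scaled to an 800-m relief; the coastline is
a contiguous ocean strip on the west edge. True conductance is the
inverse-logit of a linear+quadratic predictor with known coefficients.
Telemetry locations are per-cell multinomial draws with probability
proportional to conductance times $e^{-d/\text{decay}}$ from the release
site, jittered within the cell; there is no within-day movement
autocorrelation, which is irrelevant downstream because daily thinning keeps
one point per bird-day anyway. The sampling support excludes ocean and the
5-km site disk, and the table is salted with known counts of unproofed,
slow, fast, offshore and near-site records — one removal category per
record — so each filter's removal count can be checked against the injected
count exactly.

The default study conditions are a 101×101 grid of 1-km cells with the
release site at the centre, a 40-km ground ring at 10-km spacing (26
connections), a 30-km decay length, and 15 birds × 120 days × 12 fixes/day
(22,020 raw fixes with injections; 1,800 movement points after filtering).
The ring radius is set by the landscape extent; the full-scale 350-km
geometry is exercised analytically through the ring-placement operation,
whose node count (220) does not depend on a raster. What passing tests show:
the filters, optimiser, solver and network operations implement their
definitions exactly, and the pipeline recovers a known data-generating
process — simulated movement is "well calibrated" to the mean current map
(held-out Boyce ≥ 0.9 at these conditions). What they do not show: that
real condor telemetry follows a multinomial conductance-times-decay law,
that real covariates are Gaussian random fields, or that the published
habitat coefficients transfer — those claims need the real data this
package deliberately does not require.

## Degenerate inputs and numerical edges

All-nodata rasters, all-zero conductance surfaces, empty study areas,
degenerate (collinear) movement hulls, source = ground, disconnected
source–ground pairs, constant evaluation maps, zero-conductance cells at
reciprocal time and empty value vectors all raise immediate, named errors
rather than propagating NaNs. Records outside the mask extent are dropped
with a count by default (`off_grid = "error"` to refuse). Coordinate-descent
updates are step-capped (features live in $[0,1]$, so $|\lambda| \approx 50$
is saturation) and guarded by backtracking on the true objective, so the
gain trace is non-decreasing by construction. Laplacian solves are direct
factorisations; `Matrix` handles the sparse symmetric structure.

## Known limitations

Conductance is isotropic and static: no wind or thermals by time of day, no
seasonal structure, no social attraction to conspecifics — the circuit
treats all directions and dates alike. The Boyce evaluation inherits the
known sensitivity of windowed P/E ratios to sample size; under a null
(points independent of the map) the index is centred on zero but individual
realisations at these window settings have a standard deviation near 0.35,
so single-run values should be read with that in mind. Hinge, product and
threshold features are deliberately out of scope for the conductance model,
as are corridor-width and pinch-point analyses for the linkage stage.
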