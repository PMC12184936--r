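---
title: "Route-based noise exposure and mode-choice modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Route-based noise exposure and mode-choice modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Whether people drive, cycle or walk to work is shaped by the environments
their journeys pass through — not only by where trips start and end. This
package implements a route-based accounting of that exposure: commuting
origin–destination (OD) flows are routed over a street network, the routed
itineraries are intersected with an equal-area hexagonal tessellation
carrying built-environment and noise attributes, and each commuter becomes
one row of a trip table recording the trip distance, the average built
environment along the way, and the *share of trip distance* spent in each
ordinal road-traffic-noise class. A random forest then classifies the travel
mode (car, bicycle, walk) from these features, and the model is interpreted
through Gini importance and multiclass partial dependence on the
log-of-votes scale.

Real inputs of this kind (census OD tables, strategic noise maps, building
footprints, road centrelines, points of interest) are license-encumbered and
city-specific, so the package ships a synthetic city generator whose
mode-choice behaviour is *known by construction*. Everything downstream can
therefore be validated by parameter recovery — does the fitted model
rediscover the drivers the generator used? — rather than by reproducing any
particular city's figures.

## Pipeline and data model

Six stages, each independently runnable from persisted artifacts
(`run_stage()`) or all at once (`run_pipeline()`, `assemble_trips()`):

1. **generate** — synthetic streets, buildings, POIs, noise tiles, and OD
   flows with mode labels and commuter counts; flows with fewer than 10
   commuters are suppressed, mirroring census privacy rules.
2. **grid** — pointy-top regular hexagons of exactly 25 ha
   (edge $s = \sqrt{2A/(3\sqrt3)} \approx 310.2$ m for $A$ = 250,000 m²);
   building areas, street lengths and per-category POI counts are clipped
   or assigned into cells; each cell takes the majority noise class.
3. **route** — distance-minimal paths per mode on the mode-filtered street
   graph.
4. **exposure** — itinerary–grid intersection, per-trip feature vectors,
   expansion to one row per commuter.
5. **train** — correlation pruning, stratified 70/30 split, near-miss
   rebalancing of the training partition, (optionally tuned) random forest.
6. **interpret** — normalised Gini importance and partial-dependence
   curves.

## The synthetic city: what it emulates, and what it does not

The generator is a deliberately simple stand-in; its defaults are the
package's fixed study conditions.

* **Streets**: a jittered $k \times k$ lattice (default $\approx$ 480
  segments, 4 × 4 km), guaranteed noded at shared endpoints and connected
  per mode. Three interior rows are upgraded to *arterial*; walking is
  excluded from arterials by the default mode rules.
* **Noise**: square 50 m tiles exactly partitioning the bounding box, each
  classed by the distance from its centre to the nearest arterial through a
  fixed radius ladder (60, 132, 290, 639, 1405 m for the six-class scheme,
  loudest innermost). This reproduces the essential structure of strategic
  road-traffic noise maps — ordinal classes decaying with distance from
  major roads — without any acoustic propagation physics. With no
  arterials, everything is the quietest class.
* **Noise schemes**: opaque ordinal class sets. Built-ins: `london6`
  (<55.0, 55.0–59.9, 60.0–64.9, 65.0–69.9, 70.0–74.9, >75.0 dB; the
  printed 54.9/55.0 gap is treated as contiguous at 55.0 since dB is
  continuous) and `brisbane5` (<58, 58–63, 63–68, 68–73, >73 dB).
  Averaging-window differences between mapping programmes are out of scope;
  classes are consumed as data.
* **Buildings and POIs**: rectangular footprints with a centre-weighted
  density gradient; POIs clustered around a few centres in six categories
  (educational, recreational, medical, public services, retail, others),
  retail-heavy.
* **Flows**: origins uniform, destinations drawn towards the centre
  (workplaces cluster). Mode labels are sampled from a softmax over
  per-mode utilities, linear in straight-line OD distance (km), origin
  building density (built area in ha within 300 m), origin POI count
  (within 300 m) and the noise proximity of the straight OD corridor
  (mean of $e^{-d/200}$ over 100 m samples, $d$ = distance to nearest
  arterial). Defaults (car as reference):

  | mode    | intercept | dist/km | bldg dens | POI  | noise prox |
  |---------|-----------|---------|-----------|------|------------|
  | car     | 0         | 0       | 0         | 0    | 0          |
  | bicycle | −0.4      | −0.25   | 0.05      | 0.02 | 0.3        |
  | walk    | 2.6       | −2.0    | 0.10      | 0.03 | −0.4       |

  Softmax temperature 1. These values were chosen once to yield a
  car-majority, bicycle-minority mode mix with a
  heavy walking distance penalty, mild built-environment attraction for
  active modes, and noise attracting cycling (arterials are direct) while
  deterring walking — the qualitative regime the method is meant to
  recover. Utilities use straight-line distance because routes do not exist
  at generation time; this is a documented simplification.
* **Commuter counts**: shifted geometric, $1 + \mathrm{Geom}(1/15)$ (mean
  15), so the suppression rule at 10 bites on roughly half the flows.
  Census count distributions are not published; this choice merely
  guarantees both suppressed and retained flows occur.

What passing recovery tests therefore *shows* is that the accounting,
rebalancing, training and interpretation machinery can surface known
generative structure at desk scale. What it does *not* show is anything
about real cities: the generator has no demography, no transit, no
congestion, no calibrated acoustics, and its noise–density correlation
structure is far simpler than a real noise map's.

## Spatial conventions and numerical choices

All coordinates are planar metres; no geographic CRS support. The geometry
layer is deliberately small and fully tested against conservation oracles:
polygon clipping against convex hexagons (Sutherland–Hodgman), parametric
segment clipping (Cyrus–Beck), shoelace areas.

Deterministic tie-breaks, all conservation-preserving:

* a point on a shared cell edge counts in the lowest `cell_id`;
* a segment lying exactly on a shared edge is attributed to the lowest
  `cell_id` (overlapping parameter intervals are subtracted in id order);
* a cell split exactly 50/50 between noise classes takes the *louder*
  class (conservative exposure; tie detected at 1e-7 of the cell area);
* equal-length shortest paths take the lexicographically smallest node-id
  sequence;
* `split_trips()` and all stochastic steps derive their streams from one
  seed, so a run is reproducible from a single integer.

Cell congruence is exact by construction (every hexagon is the same shape
translated); conservation of areas, lengths and counts under gridding holds
to 1e-6 relative and is enforced in tests. The noise layer must cover each
cell's overlap with the mapped extent to within 1%, else `assign_noise()`
errors; cells wholly outside the mapped extent (the grid margin) take the
quietest class.

Trip features: "average building area / street length / POI count of the
cells intersected" is read as the *unweighted* mean over distinct crossed
cells — the closest literal reading — with a length-weighted variant behind
`trip_features(weighted = TRUE)` for sensitivity analysis. Noise shares are
normalised by the sum of traversed lengths, so every row lies on the
probability simplex to machine precision; zero-distance trips take share 1
in their origin cell's class. Trips crossing exactly one cell necessarily
have binary shares — the geometric reason very short (walked) trips
concentrate at 0% or 100% exposure.

## Routing

The router substitutes a full multimodal engine with single-criterion
shortest paths by *distance* on mode-filtered subgraphs, since every
downstream feature is distance-based; per-mode speeds, schedules and turn
restrictions would not change the exposure accounting being validated. The
criterion is a documented property of the module, not a configuration
guess. Origins and destinations connect to their nearest mode-accessible
node by straight access/egress segments included in the total distance.
Flows with no feasible route are dropped and counted in the run report.

## Modelling protocol

* **Pruning**: drop features until no pair has |Pearson r| > 0.8; from each
  offending pair the feature with the larger mean absolute correlation goes
  (ties: the later column). A keep-list pins the four POI categories
  (retail, educational, recreational, medical) that survive pruning in the
  motivating analyses. Constant columns are excluded with a warning.
* **Split**: stratified 70/30; the test partition keeps the original class
  distribution.
* **Rebalancing** (training partition only): near-miss undersampling to the
  minority-class count, distances on a z-scored copy, each majority point
  scored by its mean distance to its 3 nearest minority points. Two
  variants: `keep-closest` (the standard near-miss selection; default) and
  `remove-closest` (retain the farthest — the literal reading of removing
  majority points most similar to the minority). Both are tested; on the
  synthetic data they recover the same qualitative structure.
* **Tuning**: 3-fold stratified cross-validation over (trees, max
  features); exact ties prefer fewer trees, then fewer features. The
  default recovery configuration skips the search and fixes 500 trees with
  3 candidate features per split (≈ ⌊√p⌋ for the p = 13 trip features, and
  the tuned value of the denser-city model in the motivating analyses).
* **Forest**: `randomForest` with unlimited depth, minimum split size 2,
  Gini impurity; OOB accuracy recorded; per-class vote fractions exposed.
* **Evaluation**: 3 × 3 confusion matrix in fixed class order (car,
  bicycle, walk), reported both at the original test distribution and on a
  rebalanced copy of the test set, since either convention is defensible.

A caution on expanded tables: duplicating each flow by its commuter count
(one row per individual) means duplicates of one flow can land on both
sides of the split, so OOB and rebalanced-test accuracies are optimistic;
the original-distribution held-out accuracy is the honest headline number,
and even it inherits flow-level rather than row-level variance. The
label-permutation control in the acceptance suite is averaged over three
permutation draws for exactly this reason.

## Interpretation

**Gini importance** is the forest's mean-decrease-impurity per feature,
normalised to sum to one; ranks break ties by feature name.

**Partial dependence** maps per-class vote fractions $p_j(x)$ through a
log-of-votes transform. Two formula variants are provided because the
conventional multiclass form centres by the mean log-vote:

* `printed`: $f_k(x) = \log p_k(x) - \sum_{j=1}^{K} \log p_j(x)$
* `centered` (default): $f_k(x) = \log p_k(x) - \tfrac1K \sum_{j=1}^{K}
  \log p_j(x)$, which sums to zero over classes at every point.

The variants differ in scale and offset, never in shape. Vote fractions are
smoothed as $(v_j + \varepsilon)/(\sum_j v_j + K\varepsilon)$ with
$\varepsilon = 1/(2\,n_{trees})$, since zero-vote classes occur on probe
rows. Positive $f_k$ means the class's log-vote exceeds the across-class
average; negative means it falls below it.

Two probe strategies:

* `probe = "means"` (default): one probe row per grid value, every other
  feature held at its mean — the "controlling for the other variables by
  holding them at their means" protocol. The mean noise-share vector need
  not lie on the simplex; `renormalize_shares = TRUE` rescales it.
* `probe = "average"`: the Friedman partial-dependence estimator — clone
  the table, overwrite the feature column, average the vote fractions.
  This is what the classical forest-PDP implementations compute, and it is
  far more stable: a single probe row's vote fraction from a finite
  ensemble is a step function of the grid value.

The evaluation grid is 50 evenly spaced points between the feature's 1st
and 99th percentiles.

## Recovery properties, and a known rough edge

Under the default recovery configuration (2,000 flows, ≈ 1,100 retained
after suppression, ≈ 26,000 individuals, 500 trees, 3 features per split),
across seeds:

* trip distance is the top-ranked Gini importance;
* held-out accuracy sits far above the 1/3 chance level;
* permuting training labels collapses accuracy to chance on balanced data;
* the walk-class partial dependence on distance falls steeply overall,
  from walk-dominant votes at short distances to near-zero at the 99th
  percentile.

The walk–distance curve is, however, not *pointwise* monotone: with
roughly a thousand effective flows and 500 trees, vote-fraction curves
retain micro-wiggles (a minority of consecutive grid steps tick upward by
small amounts, even for the averaged estimator — the acceptance script
reports the measured fraction), and the log scale
amplifies wobble where votes are near zero. This is an estimator-variance
property of forest PDPs at this data size, not an accounting defect; the
corresponding strict-monotonicity check in the acceptance suite is asserted
at a 90% threshold and is expected to fail, with the measured fraction
reported by `scripts/acceptance.R`. Treat forest PDP wiggles smaller than
the vote granularity ($1/n_{trees}$) as noise when reading the curves.

## Known limitations

* Planar metric coordinates only; no geodesic or raster inputs.
* The router is distance-only and unimodal per trip.
* The generator's utilities use straight-line distance; features use
  routed distance (collinear in practice, ≈ 1.2 detour factor).
* Expanded tables duplicate rows; see the modelling caution above.
* Noise classes are ordinal labels; no dB arithmetic is performed.
* PDPs are held-at-means or data-averaged; ICE curves, two-way PDPs and
  permutation importance are out of scope.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely from generated data: unit
fixtures use a 2.5 × 2.5 km city (≈ 180 street segments, 300 buildings),
conservation and routing oracles run on seconds-scale inputs, and the
recovery analysis uses the full default configuration above (≈ 50 s per
seed on one CPU). These sizes were chosen so the whole validation cycle
stays interactive while keeping every statistical check at a sample size
where its expected behaviour is unambiguous.
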