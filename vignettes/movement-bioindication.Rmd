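---
title: "Movement-based bioindication: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement-based bioindication: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hotspotr` turns multi-species GPS telemetry of birds of prey into a
biodiversity indicator: it designates 50 m grid cells of concentrated raptor
activity, pairs each with a matched farmland control, and compares survey
biodiversity between the two site classes. This vignette is the package's
account of the underlying models, the parameters that matter, the numerical
conventions, and what the simulation-based validation does and does not
establish.

## The designation procedure

All spatial analysis happens on a square grid (default 50 m — a few times
typical GPS positioning error, and fine enough to resolve single landscape
elements). Cells are indexed 0-based `(row, col)` from the lower-left
origin of the study bounding box and are half-open on their upper and right
edges, so every point belongs to exactly one cell. Grid alignment follows
the bounding box; nothing in the method depends on a national-grid origin.

**Thinning.** Tag duty cycles differ enormously between individuals (solar
charging differs between soaring harriers/eagles and perching
buzzards/goshawks), so raw fix counts are not comparable. Tracks are thinned
per individual with a greedy rule: keep the first fix, then keep each later
fix iff at least `interval − tolerance` (default 15 − 2 min) has elapsed
since the last kept fix. The rule is idempotent and guarantees a minimum
spacing; it is the standard resampling scheme in movement ecology. A
bin-based scheme (first fix per quarter-hour bin) can keep two fixes a
minute apart across a bin boundary, which is why the greedy gap rule is
used instead.

**Usage tallies.** Per cell and season we count `n_obs` (thinned fixes),
`n_individuals`, `n_species`, and `n_days` — distinct local calendar dates
with at least one fix ("revisits"). Dates are extracted in a configurable
timezone (default UTC); timestamps are always stored UTC.

**Qualification.** A cell is a hotspot candidate when at least
`min_individuals = 3` distinct individuals of at least `min_species = 2`
species used it in the season. We read the qualification phrase as an
AND of minimums (≥ 3 individuals and ≥ 2 species), the weakest reading
consistent with its wording; both thresholds are configurable. Cells whose
largest-area landcover class is forest, water or peatland are excluded
beforehand, as are cells with an isolated perching structure (single tree,
pylon): at this spatial scale such cells attract raptors as perches rather
than foraging sites. Perch structures are an input point layer; they were
identified by inspection in the original field workflow and automating
their detection is out of scope.

**Adjacency resolution.** Qualifying cells that touch (8-neighbour "queen"
adjacency by default; 4-neighbour available) describe one activity centre.
One representative is kept per connected component: most species, then most
individuals, then most observations, and as a final deterministic tie-break
the lexicographically smallest `(row, col)`. The cascade mirrors the
designation priority (species diversity first); the lexicographic fallback
is an artifact decision needed only for full determinism.

**Spacing.** Representatives are processed in that same rank order and
accepted greedily unless strictly closer than `min_hotspot_spacing = 450` m
(centroid to centroid) to an accepted hotspot — "closer than" is a strict
inequality, so two hotspots at exactly 450 m coexist. The 450 m floor
exists because bird point counts have a 100 m detection radius and closer
sites would not be independent.

**Control selection.** Each hotspot's control lies on the circle of
`control_radius = 500` m around its centroid. Candidate cells are those
whose square the circle intersects, ordered by the azimuth of their
centroid clockwise from north (ties: nearer centroid, then smaller index).
The first cell satisfying all of the following is the control: at most
`max_control_obs = 1` tracked-raptor observation in the season, farmland
landcover without a perch flag, and at least `min_control_spacing = 500` m
from every other designated site of the season. The paired hotspot itself
is exempt from that last test — it sits at exactly 500 m, which is not
"closer than" 500 m. If the scan exhausts the ring the hotspot is reported
unpaired; the radius is never relaxed, because the matched design requires
controls at a fixed distance. Controls therefore sit within half a cell
diagonal (≈ 35.4 m) of the nominal 500 m.

Designation across seasons (e.g. designating from last spring's tracks and
verifying with this season's) needs no special mode: any usage table can be
passed to `designate_sites()` or `usage_at_sites()`.

## The statistical models

**Survey aggregation.** Birds: abundance and richness are averaged over the
two point-count visits (a plot with another number of visits is used as-is
with a warning). We also average richness rather than take the union across
visits — the protocol averages "the numbers", and averaging keeps abundance
and richness on the same footing. Small mammals: total captures over all
traps and nights, distinct species captured. Amphibians: totals over the
five transects. Plants: richness is the union of the five 1 m² quadrat
lists; diversity is the mean Jaccard similarity over the 10 quadrat pairs —
*lower* similarity means more between-quadrat turnover, i.e. higher
within-plot diversity. Two empty quadrats compare as similarity 1
(identical composition); the convention matters only for near-barren plots
and is applied consistently.

**GLMs.** Each predictor enters its own binomial GLM of site class
(hotspot = 1), fitted by IRLS to a relative log-likelihood tolerance of
1e-10 via `stats::glm`. Predictors are z-scored by default so slopes are
comparable across predictors measured in different units; raw-scale fitting
is a flag. Confidence intervals and p-values are Wald-based. Model quality
is reported both as McFadden's R² (`1 − lnL/lnL₀`, variance explained) and
Nagelkerke's pseudo-R² (rescaled Cox–Snell, goodness of fit); neither is
privileged and both are always returned. Perfect separation — easy to
produce with strong planted effects at small n — is detected and flagged
`converged = FALSE`: the slope sign is still meaningful, its magnitude and
p-value are not. No multiple-testing adjustment is applied, matching the
single-predictor-per-model design.

**Persistence.** For each space-use metric, hotspot and control values on
the *same designated cells* in a later year are compared with a two-sided
Wilcoxon rank-sum test. `W` is the rank sum of the hotspot group (midranks
under ties). The p-value is exact (via the Mann–Whitney null distribution)
when `min(n, m) ≤ 10` and there are no ties, otherwise a normal
approximation with tie correction and continuity correction is used; the
exactness threshold is configurable. Under heavy ties (e.g. many unused
cells with all-zero metrics) the test is conservative, never liberal.

## The simulator and its defaults

The generator exists so the pipeline can be validated against known ground
truth without any data download. Its defaults *are* the study conditions of
the package's validation suite and were fixed a priori; they are not tuned
per test.

- **Landscape** (`generate_landscape()`): a 5 × 5 km desk-scale rectangle
  (the original study area was 20 × 25 km) with non-overlapping rectangular
  patches of forest (45%), water (1%), peatland (3.5%) and non-farmland
  open habitat (4.5%) over a farmland background (≈ 46%) — the approximate
  class shares of a north-European farmland mosaic. Realized shares are
  kept within ±5% of target. `n_patches = 12` circular prey-rich patches of
  radius 100 m with intensity boost 5 are placed on farmland with centres
  ≥ 1 km apart, so each patch supports at most one (450 m-spaced) hotspot
  and 500 m controls never fall inside another patch. Twelve patches yield
  roughly 24 survey plots per world — small enough to simulate hundreds of
  worlds, large enough that a two-fold enrichment is recoverable (a
  power-design choice made before any validation was run; the field study
  pooled 92–147 plots).
- **Movement** (`generate_tracks()`): each individual is a central-place
  forager alternating nest bouts (15–90 min) and foraging trips (30–120
  min) through a 06:00–20:00 activity window. A trip's destination cell is
  drawn over open cells within 3 km of the nest with probability ∝
  intensity^α; fixes are emitted at the species interval (defaults 5/8/15/30
  min for the four species, emulating charge-dependent duty cycles) with
  ±30 s jitter, Gaussian within-trip wander (SD 50 m) about the destination
  centroid and GPS noise (SD 10 m). α = 0 makes destinations uniform over
  reachable open cells (the movement null); α = 4 with boost 5 concentrates
  essentially all foraging in patches. The model is a destination-choice
  device, not a mechanistic flight model: the pipeline, not raptor
  biomechanics, is under test, and the simulator only needs to concentrate
  space use with tunable strength.
- **Surveys** (`generate_surveys()`): fauna counts are negative binomial
  (dispersion size 5 — overdispersed, the field norm) with mean `baseline ×
  δ` inside prey patches and `baseline` outside (birds 8 per visit, small
  mammals 5, amphibians 5); species identities are drawn from regional
  pools (25/9/7) with geometrically decaying abundances, so richness rises
  with abundance mechanically, as in rarefaction. Plant plots draw a local
  pool (Poisson with mean 30, × δ^0.4 inside patches — pool size varies
  between plots as real vegetation does) and include each pool species in
  each quadrat with probability `1 − heterogeneity`; heterogeneity is 0.35
  outside patches and is raised inside so that enriched plots have both
  higher richness and lower quadrat similarity. δ = 1 is an exact null.
  The patch effect is binary in/out of the patch radius; smooth kernels are
  deliberately avoided so the ground truth is unambiguous.

All generators take explicit seeds and restore the caller's RNG state.

## What the validation shows — and what it does not

The test suite validates, at desk scale (grids ≤ 30 × 30 for oracle
equivalence; 3 km null worlds over 14-day seasons; 5 km enriched worlds over
21-day seasons — sizes chosen so hundreds of replicates stay cheap):

- exact agreement of the full designation algorithm with an independent
  brute-force reference on hundreds of randomized worlds, plus the rule
  invariants (qualification, strict spacing, farmland-only ≤ 1-observation
  controls, determinism);
- exact agreement of the Wilcoxon machinery with exhaustive permutation
  enumeration, and of the logistic ML fit with a derivative-free
  grid-refinement oracle;
- calibration: in α = 0, δ = 1 worlds the designated "hotspots" show no
  survey effects (per-model false-positive rate at the nominal 5% level)
  and persistence p-values behave as a conservative null;
- power and recovery: in α = 4, δ = 2 worlds, designated hotspots coincide
  with true patch centres and all planted effect signs are recovered in
  ≥ 95% of worlds.

One calibration property is reported honestly as failing at its stated
tolerance: over 500 replicates at n = 150 plots the *mean* of the plain ML
logistic slope overshoots the planted β\* = 0.6 by ≈ 0.03 — the classical
O(1/n) bias of the logistic MLE, larger than two Monte-Carlo standard
errors of the mean at that replicate count. CI coverage (93–96%) is
unaffected. A bias-reduced (Firth) fit would remove it but would no longer
be the plain-GLM analysis this package mirrors.

Passing these checks shows the *pipeline* is correct and calibrated under
the generator's assumptions. It does not show that real raptors weight prey
patches as a power of prey intensity, that real enrichment is a clean
two-fold multiplier, or that real surveys are negative binomial with
geometric abundance structure; transferring conclusions to field data rests
on the original study design, not on these simulations. The simulator also
omits fix-quality filtering, outlier speeds, nest-vicinity effects and
within-trip travel geometry, all irrelevant to cell-level tallies at 15-min
resolution but potentially relevant to other uses of the tracks.

## Numerical conventions and degenerate inputs

- Distances are centroid-to-centroid Euclidean metres in a projected CRS;
  geographic input is projected with a local equirectangular projection
  (sub-metre error at study scale). All "closer than" rules are strict
  inequalities.
- Landcover classification is by largest area overlap; an exact area tie
  makes the cell ineligible (conservative). Rectangle overlaps are computed
  exactly; general polygons via Sutherland–Hodgman clipping and the
  shoelace formula.
- Duplicate fixes: exact duplicates are dropped silently with a count;
  same-timestamp different-coordinate fixes keep the first with a warning.
- Empty inputs (no fixes in a window, no qualifying cells, an exhausted
  control ring, a missing comparison year) are reported outcomes, never
  errors; genuinely malformed inputs (missing columns, unknown landcover
  classes, unparseable timestamps, constant predictors, empty Wilcoxon
  groups) fail fast with named errors.
- Designation output is fully deterministic: rerunning a configuration
  reproduces site files byte for byte.

## Known limitations

- No fix-quality (HDOP) or speed filtering; no behavioural-state
  classification — tracks are assumed pre-cleaned.
- One contiguous study area per call; kernel/utilization-distribution
  estimators and habitat-selection models are out of scope.
- GeoJSON and CSV are the supported geodata formats (polygons with a
  `class` attribute, point layers for perches); interior rings are not
  supported.
- Whether fixes near nests should be excluded before designation is left
  to the user (no such filter is applied); likewise the choice of season
  windows for qualification is configuration, not convention.
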