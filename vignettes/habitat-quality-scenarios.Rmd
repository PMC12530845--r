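---
title: "Methods: land-use change accounting, habitat quality and scenario simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-use change accounting, habitat quality and scenario simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(luhq)
```

`luhq` couples four models that are usually run as separate desktop tools —
land-cover transition accounting, an InVEST-style habitat-quality model, a
Markov land-demand projection and a patch-generating cellular-automata (CA)
allocator — into one scriptable, seeded pipeline over categorical rasters.
This vignette documents the models, their assumptions, the tunable
parameters, and the design choices taken where the methods literature leaves
the details open.

## Data model

All rasters live on a `grid_spec`: row-major, origin at the top-left cell
corner, square cells of `cell_size` metres, cell centres at
`corner + (k + 0.5)·cell_size`. Land-cover maps (`lulc_map`) carry integer
codes 1–7 (farmland, forest, shrub, grassland, water, construction, barren);
continuous surfaces are `raster_layer`s. Cell areas are `cell_size²/10⁶` km²
and every table the package emits is in km². Rasters are exchanged as
plain-text Esri ASCII grids, whose header carries exactly the grid geometry
the package needs; round trips are bit-exact for integer maps. Two grids are
treated as co-registered when dimensions match and origin/cell size agree to
1e-6 of a cell, absorbing floating-point geotransforms.

Cells that are nodata in *either* epoch are excluded from both marginals of
the transition matrix, so row sums equal first-epoch class areas, column
sums equal second-epoch areas, and the grand total is the jointly valid area
— the conservation identities the test suite asserts on every synthetic
pair. Change rates are `100·(A₂ − A₁)/A₁`, undefined (NA) for classes absent
at the first epoch.

## Habitat quality

Threat sources are cells of the threatening classes themselves: farmland
(maximum effective distance 1 km, weight 0.4, linear decay) and construction
land (10 km, weight 1, exponential decay). Decay kernels are

$$i = 1 - d/d_{max} \quad\text{(linear)},\qquad
  i = \exp(-2.99\, d / d_{max}) \quad\text{(exponential)},$$

both exactly zero beyond $d_{max}$. Distances are Euclidean,
centre-to-centre, computed with an exact distance transform
(`EBImage::distmap`, verified against a brute-force all-pairs loop to
1e-9 in the tests).

Degradation at cell $x$ of class $j$ is the weight-normalised sum over
threats of $i_r(x)\,\beta_x\,S_{jr}$, clamped to [0, 1]; quality is
$Q = H_j\,(1 - D^2/(D^2 + k^2))$ with class suitabilities $H_j$ and
sensitivities $S_{jr}$ from the default table (forest suitability 1,
water 0.7, farmland 0.3, construction 0).

Three choices here were genuinely open:

* **Aggregation over sources.** Degradation formulas of this family are
  often typeset with ambiguous summation indices. We take, per threat, the
  decay weight of the *nearest* source cell (equivalently the maximum of
  $i_{rxy}$ over sources $y$). This reproduces the screened-threat anchor
  points used for validation — a farmland cell far from construction scores
  exactly $H_1 = 0.3$ regardless of how much farmland surrounds it, because
  farmland is insensitive to its own class. A mean-over-sources variant is
  available (`habitat_config(aggregation = "mean")`) for sensitivity
  analysis; the nearest-source rule is the contract and the brute-force test
  oracle uses the same rule.
* **Half-saturation constant.** $k$ is the degradation level at which
  quality halves; it is rarely reported. We default to $k = 0.5$, the common
  InVEST default, and expose it. The four validation anchors have $D = 0$ or
  $H = 0$ and are therefore insensitive to $k$ (asserted in the tests).
* **Accessibility.** $\beta_x$ defaults to 1 everywhere; a raster override
  is accepted.

Grades use left-closed intervals at cut points 0.298 / 0.698 / 0.984
(Low, Medium, Good, Excellent). Written strictly, a top interval
`1 > Q ≥ 0.984` excludes $Q = 1$ from every grade; we include 1 in Excellent
and note the choice here rather than make it silently. Cut points can also
be derived from the data by Jenks natural breaks: a Fisher-style dynamic
programme minimising within-class SSE, deterministic for a fixed sample, and
checked in the tests against exhaustive partition search on small samples.
For large rasters the caller subsamples (a few thousand values suffice;
the optimisation is $O(kn^2)$). Landscape means of quality and degradation
are unweighted means over all valid cells, all classes included.

## Markov demand and scenarios

Row-normalising the transition matrix gives the transition-probability
matrix; classes with zero initial area get identity rows with a warning.
**One Markov step spans the calibration period.** When the projection
horizon equals the calibration window (e.g. a 14-year history projected 14
years forward), `steps = 1` is the faithful choice; the package does not
annualise probabilities by matrix roots, and `steps` is exposed for longer
horizons.

The ecological-priority (EP) preset encodes protective multipliers on
targeted off-diagonal transitions: farmland→{forest, shrub, grass, water}
×1.5; forest→all but water ×0.4; shrub→all but water/forest ×0.6;
grass→all but water/shrub/forest ×0.6; water→all but shrub/forest/grass
×0.6 ("reduced by 60%" read as ×0.4, "increased by 50%" as ×1.5, "reduced
by 40%" as ×0.6). After rescaling, each row's diagonal absorbs the residual
(persistence changes, the named transitions keep their adjusted values); in
the degenerate case of off-diagonals exceeding 1 they are rescaled
proportionally and the diagonal set to 0. By construction the preset never
raises forest→farmland nor lowers farmland→forest, and every operation
preserves row-stochasticity and total area (both asserted).

## Expansion mining and allocation

For each growing class, positives are all cells that newly converted to it
between the epochs; negatives are a seeded background sample (default 1:1)
of the remaining valid cells. Features are raw continuous drivers
(tree ensembles are scale-free) and one-hot-encoded categorical drivers. A
seeded probability random forest (`ranger`) supplies the development
probability at every cell and impurity importances normalised to sum 1. The
forest considers half the features per split by default — with few drivers
and a crisp expansion rule, root splits on uninformative features blur the
probability surface, and the tests require a noise-free separable rule to be
recovered with probabilities above 0.9 / below 0.1.

The allocator is a deliberately simplified multi-seed CA: the exact
scheduling of the released PLUS-style software (threshold constants,
patch-size distributions) is not public, so parity with it is explicitly not
a contract. What is contracted, and tested, are the behavioural invariants:

* candidate score = development probability × (neighbourhood density +
  uniform patch-seed term in [0, `patch_seed_fraction`]), gated by the
  conversion-cost matrix (default: all transitions allowed);
* cells convert in score order, only toward classes short of demand and
  only out of classes above demand, while the score exceeds a global
  threshold (initial 0.5) that decays ×0.5 whenever an iteration converts
  nothing;
* restricted-mask cells holding a protected class (forest, shrub, grass,
  water by default) never convert — asserted every iteration;
* cell counts are conserved; on feasible fixtures final areas match demand
  to the tolerance (0 km² by default, with demand rounded to whole cells by
  largest remainder); infeasible demand terminates with a per-class
  residual and a warning rather than an error;
* identical seeds give identical outputs.

The neighbourhood term is the class fraction in the (2r+1)² window
(default r = 2), computed by integral image with truncated edge windows.

## Synthetic landscapes

The generator emulates the statistical structure the analysis assumes — a
mosaic ~90% forest with farmland at its edges, small water / construction /
shrub / grass / barren fractions, smooth correlated driver fields and a
core-area redline mask — not any real terrain. A Gaussian-smoothed seeded
random field (correlation length `patch_scale`, default 8 cells) is cut at
the target class-fraction quantiles, ordered so farmland bands abut forest.
Elevation shares 70% of its variance with that field (forest sits high);
slope/aspect are its finite-difference gradient; roads are seeded random
walks rasterised and distance-transformed; population and GDP decay with
elevation; temperature follows a lapse rate; soil classes are elevation
bands. Change generation converts an exact, auditable number of cells per
rule, edge-biased rules preferring cells adjacent to the destination class
and at low elevation — which makes recovered transition probabilities exact
by construction and gives the parameter-recovery tests known ground truth.

Passing tests on these landscapes show the pipeline's accounting,
estimation and allocation are correct under known structure; they do not
show that the habitat parameters or the mined expansion rules transfer to
any real region, and the generator makes no topographic or hydrological
claims.

## Problem sizes and numerical notes

The test suite exercises grids from toy (2×2) through 512×512 for
class-fraction checks and ~320×320 (≈10⁵ cells) for Markov parameter
recovery, with allocation toys at 20×20–48×48 — sizes chosen so the full
suite runs in well under a minute while still separating sampling error
from bias (recovery tolerance is 4σ of the multinomial error at the
smallest class count). Degradation tolerances: the distance transform is
exact, so oracle equivalence is asserted at 1e-9; proportions sum to 1
within 1e-9; demand conservation within 1e-6 km². Ties in allocation scores
are broken by cell index under a fixed seed, making runs reproducible
across platforms.

## Known limitations

* Threat intensity is binary presence; weighting sources by an intensity
  raster, habitat-rarity scoring and route-based decay are out of scope.
* No reprojection or resampling: all inputs must be co-registered.
* The CA is a mechanism-faithful simplification; absolute agreement
  statistics against maps simulated by other software are not comparable.
* Markov projection ignores demand feedback (no optimisation against
  socio-economic targets).
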