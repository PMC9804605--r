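---
title: "Measuring habitat structural complexity: methods, conventions and known biases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring habitat structural complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(habcomplex)
```

# Scope and model

`habcomplex` computes the two geometric complexity metrics most used in
ecology — fractal dimension *D* and rugosity *R* — together with the
simpler geometric descriptors (height range, terrain ruggedness, slope,
vector dispersion) and an informational metric (Shannon entropy of habitat
composition). All surface metrics consume a `heightmap`: a rectangular
grid of elevations with one physical `cell_size`, row-major with origin at
the top-left and cell centres at `(i − 0.5, j − 0.5) · cell_size`. A
heightmap is a 2.5D object: each planar position carries exactly one
elevation, so overhangs and interstitial spaces are unrepresentable. That
is a representational limit of DEM-based complexity measurement, not an
approximation the package makes silently.

# Fractional Brownian relief and ground truth

Self-affine fractional Brownian motion (fBm) with Hurst exponent
*H* ∈ (0, 1) is the standard model of fractal terrain: increments over lag
*a* scale like *a*ᴴ, a surface has dimension 3 − *H*, a 1D profile (or a
planar "coastline", such as the median level set of a surface) dimension
2 − *H*. Two generators are provided:

* `midpoint_displacement()` — diamond–square subdivision. Both diamond and
  square points receive a Gaussian displacement whose standard deviation is
  multiplied by 2⁻ᴴ at each halving of the lateral scale; corners start at
  0, grid side is 2ˡᵉᵛᵉˡ + 1.
* `spectral_fbm_surface()` — Fourier synthesis: white Gaussian noise
  filtered with amplitude |f|^−(H+1), giving a radially averaged power
  spectrum ∝ f^−(2H+2). Synthesis happens on the enclosing power-of-two
  periodic grid and is cropped to the requested odd size.

**What a green test does and does not establish.** Both generators are
standard *approximations* of fBm with documented artefacts: diamond–square
"creases" (points are displaced once and never refined), which makes its
increment scaling read roughly 0.1 low in *H* at *H* ≈ 0.7; the cropped
spectral field reads high at low *H*. The increment-variance property test
therefore asserts recovery of *H* within a fixed band of 0.15 plus strict
monotonicity across *H*, not pure Monte-Carlo error. Relatedly, the
spectral-slope oracle applies a Hann window before the periodogram
regression, because the non-periodic crop otherwise leaks power and
flattens steep spectra. Simulated maps also differ from real scans in ways
the tests cannot speak to: no instrument noise, no gaps, no anisotropy, no
multifractality.

**Seeding.** One root seed drives everything. Replicate streams are derived
by a fixed integer hash (`child_seed`, a 32-bit LCG composition of root
seed and replicate index), so replicate *r* is reproducible in isolation
and independent of how many replicates were requested.

# Box-counting: protocol choices

`box_count()` counts, for each box edge ε (cells) and each grid origin,
the boxes containing at least one foreground cell; the curve statistic is
the mean across origins. Defaults follow the recommended protocol:

* **Random origins** drawn uniformly from [0, ε)², never aligned to
  features of the set (`n_origins = 16` is ample; the origin-to-origin
  standard deviation of N(ε) shrinks like 1/√n of a mean).
* **Strict edge rule**: boxes straddling the map edge are excluded, so no
  region outside the measured window is counted. The complementary
  `edge_rule = "permissive"` keeps partial edge boxes; it exists to
  reproduce the classic naive protocol (below) and is never the default.
* **Dyadic scales** ε = 2, 4, 8, … by default; arbitrary grids accepted.
* **Intermediate window**: `intermediate_scale_rule(side)` rescales the
  empirically reliable 32–128-cell window of a 4097-cell map
  proportionally — `(round(side/128), round(side/32))`, clamped to ≥ 2 —
  and refuses maps too small to put three dyadic scales in the window.

`fit_dimension()` is an unweighted OLS of log N on log ε over the chosen
range; heteroskedasticity is *reported* (Breusch–Pagan score flag), not
silently reweighted, so estimates stay comparable across protocols.
Nonlinearity is tested by a quadratic-term t-test and residual normality
by Shapiro–Wilk (only with ≥ 5 scales; with 3–4 scales the flags are `NA`
rather than noise). Estimates are never clamped to [1, 2] or [2, 3]:
estimator bias must stay visible.

**The naive protocol.** The bias study's `box_naive` arm deliberately
commits every sin the recommended protocol avoids: the full available
scale range from ε = 1 (exposing the finite-resolution small-scale bias)
up to half the map side, a grid aligned at the map corner, and the
permissive edge rule (counting box-grid regions that extend beyond the
measured set). The last point matters more than it may seem: a median
level-set boundary spans its whole window, so under the strict rule the
large-scale counts saturate at the (side/ε)² ceiling and the naive fit
can only be pulled *upward*; the classic downward large-scale bias
appears precisely when partial boxes are included. With the full naive
protocol the familiar compression emerges — low dimensions overestimated,
high dimensions underestimated, crossover mid-range.

# The level-set boundary convention

`binarize(surface, "median")` splits a surface at its median;
`level_set_boundary()` extracts the coastline whose dimension is 2 − *H*.
Two conventions are exposed. `sides = "inner"` (the default) marks
foreground cells with an opposite 4-neighbour — the one-cell inner
perimeter, matching the intuitive examples (a filled square's boundary is
its one-cell-thick perimeter; an isolated cell is its own boundary).
`sides = "both"` marks cells of either class adjacent to the interface.
The bias study uses `"both"`, because it is the faithful pixel cover of
the continuous level curve: every box the curve passes through contains a
marked cell, which is the object whose box counts estimate 2 − *H*. With
the inner perimeter the dashed, one-sided cover visibly under-counts at
intermediate scales (estimates drop ~0.15–0.25 at desk scale) and the
naive protocol loses its low-D overestimation. Measuring the *filled*
excursion set instead is possible but pointless for dimension estimation —
its dimension is 2 by construction — and the package does not do it
anywhere.

# Koch rasters

`koch_curve_raster()` iterates the classic construction (4ᵏ segments) and
draws it with threshold-free line drawing: every cell a segment passes
through is set, so box counts cannot depend on a grayscale cut-off. The
curve is centred on a square grid with a background margin (default
raster_size/16). The margin is not cosmetic: box-counting excludes boxes
straddling the map edge, so a curve touching the edge gets truncated at
large ε and its fitted dimension inflates (≈ 1.38 instead of ≈ 1.26 at
4096 px). With the margin at least one maximal box size wide, the
6-iteration anchor reads 1.245–1.263 across origin seeds against the
analytic log 4 / log 3 ≈ 1.262.

# Variation method

For window half-width ε, the oscillation at a cell is max − min of heights
over the square (Chebyshev) window centred there, truncated at edges;
V(ε) is the mean over cells and the log–log slope of V estimates *H*, so
D = embed − slope (3 − *H* for surfaces, 2 − *H* for profiles). The
square window makes the filter separable and exact; sweeps over increasing
radii are computed by filter composition (radius doubling costs two
clamped translates per axis), so a dyadic sweep is O(log ε_max) matrix
operations. A perfectly flat input has V ≡ 0 at all scales and raises an
explicit error — its dimension is undefined by this method.

# Rugosity

* **Surface area**: each cell quad is triangulated along *both* diagonals
  and the two areas averaged, removing the diagonal-orientation bias of a
  single triangulation. Planar area is the quad extent
  (rows − 1)(cols − 1)·cell². R ≥ 1 to machine precision.
* **Slope correction**: a least-squares plane is fitted to the heights and
  the planar denominator becomes the window's area projected onto that
  plane (planar area × secant of tilt). Any plane scores exactly 1; a
  tilted rough surface scores within ~1% of its untilted self. The
  correction projects rather than rotating the heights, keeping the planar
  area well defined.
* **Multi-resolution**: `coarsen()` aggregates f×f blocks by their mean
  (subsampling is available behind a flag but aliases high-frequency
  relief, which is why it is not the default), then recomputes R; block
  averaging can only remove relief, so R is non-increasing in grain.
* **Area decoupling**: since A = R·L², a raw richness-on-R regression
  inherits the species–area relationship. `area_decoupled_regression()`
  fits log S = a·log A + b·log R + c and flags collinearity (condition
  number > 1e8 or an inestimable coefficient) instead of failing.

# Terrain metrics

TRI is the interior-cell average of the RMS height difference to the 8
neighbours; edge cells are excluded rather than padded. Slope/aspect use
central differences over 2·cell_size; aspect is `NA` where the gradient
vanishes. Vector dispersion uses the same facet triangulation as rugosity;
with mean resultant length R̄ of the upward unit normals, the default
statistic is 1 − R̄ (0 for any plane). The Fisher-statistics variant
(N − |Σ|)/(N − 1) is available via `variant = "fisher"`; both conventions
circulate in the morphometrics literature and they agree to ~10⁻³ for
realistic facet counts, so the choice of default is cosmetic but fixed.

# Entropy

`shannon_entropy()` is fixed to base-2 logarithms (bits); natural-log
output is a conversion (`bits_to_nats()`), never the stored value. Counts
with pᵢ = 0 contribute zero. Composition entropy ignores spatial
arrangement by design; the documented `adjacency_pair_entropy()` extension
scores arrangement through unordered label pairs on 4-neighbour
adjacencies (ordered maps score lower than random mixtures of the same
composition). Richer correlation-aware arrangement statistics are out of
scope.

# The estimator-bias study

`run_bias_study()` simulates, for each Hurst value and replicate, one
surface; box protocols run on the two-sided median level-set boundary
(true D = 2 − H), variation protocols on the raw surface (true D = 3 − H)
— the two method families are evaluated on different representations of
the same simulation, and the truth bookkeeping is per protocol. The
desk-scale default (1025² maps, H = 0.1…0.9, 10 replicates, ≈ 1 min) is a
scaled-down surrogate of the full design (4097², H = 0.01…0.99, 100
replicates), which is one `study_config()` away and uses the identical
code path. At desk scale the qualitative results are stable: the
intermediate-window protocol tracks the 1:1 line with roughly half the
naive protocol's mean absolute error and remains strictly monotone in the
true dimension; Fourier-synthesis maps give the same intermediate-scale
optimum with larger errors than midpoint-displacement maps.

# Numerical and degenerate-input policy

Flat surfaces: rugosity 1, TRI 0, dispersion 0, variation dimension an
explicit error, binarization one class with an empty (flagged) boundary.
Empty-foreground maps refuse box-counting with a clear message. Ties in
scaling curves are fitted as-is (no deduplication); zero statistics inside
a fit range are an error rather than a silent log(0). Profile reading
requires uniform spacing to 1e-9 relative. Dimension estimates are never
clamped. All CLI subcommands are pure functions of (inputs, options,
seed) and write byte-identical CSV on repeated runs.

# File formats

Rasters are ESRI ASCII grids (plain text, exact round-trip at full double
precision for heights); profiles and compositions are CSV. GeoTIFF and
16-bit PNG are not supported in this build: no raster codec package is
available in the target environment, and a hand-rolled binary codec would
be worse than none. No projected-CRS handling is attempted.

# Known limitations

* 2.5D only: overhangs/interstitial volumes are invisible to every metric
  here.
* Real objects are at best close to fractal over a window of scales; use
  `assess_fractality()` (≥ 2–3 decades and agreeing piecewise fits) before
  interpreting any D.
* Simulated ground truth is itself approximate (see above); bias-study
  conclusions are about estimator *orderings*, not third-decimal values.
* Composition entropy depends on the element classification chosen by the
  user; that subjectivity is inherent to informational metrics.
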