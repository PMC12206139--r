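---
title: "Vessel-sinusoid separation and 3D morphometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-sinusoid separation and 3D morphometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Optical-resolution photoacoustic microscopy resolves the liver
microvasculature label-free, using hemoglobin as endogenous contrast. The
resulting volumes mix two compartments with very different biology: hepatic
sinusoids — fenestrated exchange capillaries, typically 3–5 µm in diameter,
forming a dense mesh in the shallow tissue — and wall-bearing vessels
(portal and central vein branches, ≥ 20 µm) rising from deeper layers.
Image-wide statistics conflate the two: vessel signal inflates apparent
sinusoid radius and density, and sinusoid clutter obscures vessel counts.
`hepatovasc` separates the compartments and quantifies each, so that
progressive sinusoid rarefaction (as in steatohepatitis models) can be
tracked without cross-contamination.

Conventions: volumes are arrays indexed `(z, y, x)` with `z = 1` the
shallowest slice; all physical outputs are in µm-based units derived from
the voxel spacing. The analysis chain is fully deterministic; only the
phantom generator consumes a random seed.

## Depth-compensating enhancement

Photoacoustic amplitude decays with depth (absorption and scattering of
both light and sound). Per Z-slice we record the 1st and 99th intensity
percentiles (type-7 quantiles, i.e. linear interpolation between order
statistics); the slice with the widest `I99 − I1` range becomes the
reference, and every other slice is mapped onto the reference's intensity
distribution by a monotone quantile map. The map interpolates the full
empirical quantile function rather than a fixed-bin histogram: this makes
matching exact (a slice of the same size acquires the reference's
intensity multiset exactly), is monotone by construction, idempotent up to
interpolation error, and leaves degenerate (constant) slices untouched. An
optional `bins` argument coarsens the map to a fixed number of quantile
knots when memory or speed matters.

The method assumes slice *content* is comparable across depth, so that
distribution differences reflect attenuation. When content itself changes
strongly with depth (e.g. a test object whose deep slices are mostly one
large vessel), forcing every slice onto the reference distribution
redistributes foreground mass incorrectly — which is why the package's
clean-phantom recovery analyses run with `enhance = FALSE`: with no
attenuation there is nothing to compensate, and the confound would
dominate. The per-slice SNR profile
(`20·log10(mean(foreground)/sd(background))` dB) is provided to check the
effect of enhancement; its foreground/background split must be supplied by
the caller since the acquisition defines no canonical signal region.

## Vessel separation by erosion-radius selection

Grayscale erosion (voxelwise minimum over a discrete ball, anisotropy-aware
via the spacing) with a ball radius near the sinusoid radius suppresses the
sinusoid mesh while only shrinking vessels. Two summary curves guide the
radius choice over a sweep (default 1–8 µm in 0.5 µm steps):

* mean intensity difference `MID(r) = |mean(eroded) − mean(original)|` —
  how much signal erosion removed;
* intensity retention `IR(r) = Σ eroded / Σ original` — how much survives.

Both curves are min–max normalised over the sweep and the selected radius
is where the normalised curves cross, both near 0.5. Note that the two
metrics are affinely related (`MID = mean(I)·(1 − IR)`), so after min–max
normalisation they are exact mirror images and the crossing is precisely
the radius at which intensity retention reaches the midpoint of its range
over the sweep — the point where half of the erodible (normalised) signal
is gone. We keep both metrics because each is interpretable on its own and
both are part of the module's surface; the redundancy also provides a
built-in consistency check (`mid_norm + ir_norm = 1`).

This midpoint view predicts where the crossing lands: with ~30 µm vessels,
vessel retention falls roughly like `((a − r)/a)²` (radius `a`), so the
crossing sits in the 3–5 µm band exactly when the sinusoid compartment
carries less than about 45% of total intensity. The package's sweep
calibration phantom is therefore a vessel-dominated field (four 28–30 µm
trunks, 4 µm sinusoids at density 0.05, no degradation); measured
crossings (~3.5 µm) match the closed-form prediction. In sinusoid-dominated
fields the crossing shifts below 3 µm — a property of the statistic, not a
failure of the implementation.

After erosion at the selected radius (4 µm by default, matching the
sinusoid radius scale), vessels are segmented with an adaptive local-mean
threshold: a voxel is foreground iff its intensity exceeds the mean within
a sliding window (default 25 µm cube) scaled by `(1 − offset)`
(default offset 0), *and* exceeds a global floor of 5% of the volume
maximum. The floor is needed because, far from any structure, the local
mean of an eroded volume is ≈ 0 and a pure local-mean rule would mark any
positive residue as foreground. Components smaller than the median
component volume (26-connectivity) are then removed — a robust filter for
residual sinusoid fragments, which are both numerous and small, so the
median sits well below the vessel sizes. Finally the vessel mask is
dilated back by the erosion radius (erosion + thresholding + dilation ≈
opening): erosion shrinks every vessel by `r` in radius, and without
restoration the mask would be systematically thinner than the true vessel
everywhere.

## Sinusoid separation

The vessel mask, scaled to the volume's intensity maximum, is subtracted
voxelwise from the enhanced volume: vessel voxels go non-positive,
sinusoid voxels keep their intensity. Negatives are clipped to zero, and
the remainder is enhanced with a Frangi-type multi-scale Hessian
tubularness filter: at each scale σ (defaults 0.5–2.5 µm, spanning
sinusoid radii) the Gaussian-derivative Hessian's eigenvalues
(`|λ1| ≤ |λ2| ≤ |λ3|`) form

```
V = (1 − exp(−Ra²/2α²)) · exp(−Rb²/2β²) · (1 − exp(−S²/2c²)),
```

with `Ra = |λ2|/|λ3|` separating plates from lines, `Rb = |λ1|/√|λ2 λ3|`
penalising blobs, `S` the Frobenius norm suppressing noise (`c` = half the
maximal `S` at that scale), `α = β = 0.5`, bright-tube polarity
(`λ2, λ3 < 0`), and the voxelwise maximum taken over scales. The response
is adaptively thresholded like the vessel stage (with a 5% response
floor), and the sinusoid mask is forced disjoint from the vessel mask as a
hard postcondition.

## Skeleton-graph morphometry

The sinusoid mask is thinned to a one-voxel-wide centerline by sequential
deletion of *simple points* — voxels whose removal changes neither the
number of 26-connected foreground components in their neighbourhood nor
the 6-connected background topology — cycling through the six face
directions until stable, with curve endpoints preserved. This keeps the
component count and holes of the input (topology preservation) while
reducing tubes to centerlines.

Skeleton voxels with a 26-neighbour count other than 2 become graph nodes
(endpoints and junctions); maximal degree-2 chains become branches with
physical path lengths (summed inter-voxel centre distances). Metrics
follow the cylinder model:

* length = skeleton voxel count × mean in-plane spacing;
* volume = mask voxel count × voxel volume;
* radius = `√(volume / (π · length))`;
* tortuosity = per-branch Euclidean end-to-end distance over path length —
  a *straightness* index in (0, 1] (1 = straight) — aggregated over
  branches weighted by path length;
* density `D = V_S / (V − V_L)`: sinusoid volume over the non-vascular
  volume, so vessel changes do not leak into the density.

Two definitional choices deserve note. First, headline length uses the
voxel-count convention while tortuosity denominators use true path
lengths; both are exposed per branch. Second, tortuosity is evaluated per
branch because an end-to-end distance is ill-defined for a loopy
component. On a dense mesh the junction spacing is a few µm and short
branches are inherently near-straight, so length-weighted branch
straightness on realistic meshes sits around 0.8–0.9; markedly smaller
published values arise when the ratio is taken once per connected
component (one chord over the summed length of all branches), which is a
different statistic. Calibration is therefore tested on constructed
geometry: a straight branch has straightness exactly 1 and a voxelized
semicircle approaches `2/π ≈ 0.637` (within ~5%, the digital-path length
inflation of voxel arcs).

## Branch classes and fractal dimensions

Branches are classified globally and topologically: a branch with an
endpoint of degree 1 is **dead-end** (terminal path, suggesting obstructed
flow); among branches joining two junctions, a branch sharing a junction
with ≥ 2 other junction–junction branches is **complex** (part of a
multi-segment conduit), otherwise **crossing** (an isolated connector).
The rule is deterministic and reproduces the intended examples (a Y is all
dead-ends; an H is four dead-ends plus one crossing).

Per class, the box-counting fractal dimension is computed on the class's
centerline voxels: origin-anchored partitions into cubes of side `L`
(dyadic 1–32 by default), occupied-box counts `N(L)`, and FD = the
least-squares slope of `log N` versus `log(1/L)`. Sizes where the count
has saturated (`N = 1`) or not left voxel resolution (`N` = voxel count)
are excluded from the fit to avoid plateau bias. Calibration: a 256-voxel
line fits to FD ≈ 1, a filled 64³ cube to FD ≈ 3, a single voxel to 0.

## Sinusoidal coverage of vessels

Vessel instances are 26-connected components of the vessel mask. For
instance `i`, `Z_max` is its deepest occupied slice; the sinusoid mask is
cleared from `Z_max` downward (the deepest vessel layer itself included),
leaving only canopy strictly above the vessel bottom. A vessel voxel
counts as covered when the restricted sinusoid mask has at least one voxel
in the same `(x, y)` column strictly above it; the coverage rate `R_i` is
the covered fraction of the instance's voxels, implemented with a
top-down cumulative presence map that provably equals the per-column
enumeration. Because the separated masks are disjoint in 3D, a literal
voxelwise AND would always be zero; the columnar (projective) reading is
the one that makes the overlay meaningful, matching the canopy geometry of
sinusoids enveloping vessels from above. Rates strictly above 0.5 classify
a vessel as high-coverage (HC), ties and below as low-coverage (LC).

## GLCM image-quality score

For comparing imaging configurations, 2D maximum-amplitude projections are
scored with gray-level co-occurrence statistics: the image is quantised to
64 levels over its own range; co-occurrences over the four distance-1
offsets are symmetrised, pooled and normalised; contrast
`ΣP(i,j)(i−j)²`, entropy `−ΣP log2 P` and homogeneity `ΣP/(1+|i−j|)`
are extracted. The composite rewards contrast and entropy and penalises
homogeneity — `raw = norm(contrast) + norm(entropy) + (1 − norm(homogeneity))`
with min–max normalisation across the compared set — and is divided by its
maximum so the best image scores exactly 1. The combination rule is a
declared design choice (no canonical formula exists); it is monotone in
each feature in the direction sharper, information-richer images score
higher, verified on blur ladders.

## The phantom generator

Because no public volumes of this kind exist, the package generates
synthetic liver-microvasculature phantoms with voxel-level ground truth:

* **Vessels**: a few (default 3) quadratic-Bézier trunks of radius
  10–15 µm rising from the deepest slices, each confined to its own
  lateral grid cell with a margin larger than the default erosion radius,
  so instances can never merge, even after mask dilation.
* **Sinusoids**: tubes of radius 1.5–2.5 µm (3–5 µm diameters) grown as
  curved random walks (per-walk circular-arc curvature of radius 7–25 µm
  plus directional noise at persistence 0.75), seeded 70% of the time from
  existing centerline points (branching) with 35% loop closure to nearby
  tubes. Walks stay ≥ 6 µm from the volume border so border shells cannot
  imitate thick structures. Walks are rasterised in batches and the
  *realised voxel-counted* sinusoid volume drives the stopping rule, so
  the realised density lands within a few percent of the target
  regardless of walk overlap.
* **Degradation**: soft (partial-volume) rasterisation with a one-voxel
  edge ramp; exponential depth attenuation `exp(−µ·z)` with µ = 2 mm⁻¹ by
  default (a deliberate simplification of lipid-dependent attenuation);
  additive Gaussian noise with sd = 10% of the intensity scale, clipped at
  zero.
* **Stages**: presets scale the sinusoid density target (normal 0.091,
  early 0.056, mid 0.020, late 0.012 — the rarefaction trajectory of
  progressive disease) and walk continuity (1.0 / 0.85 / 0.6 / 0.4, with
  low-continuity walks fragmented), so later stages are sparser and more
  broken.

Generation is deterministic per seed (the generator saves and restores the
global RNG state). What the phantom does *not* emulate: acoustic
speckle and reconstruction artifacts, the system PSF (tubes have sharp
soft edges rather than resolution-limited profiles), spatially varying
attenuation, vessel wall contrast, and anatomically realistic lobular
topology. Passing the phantom regressions therefore demonstrates the
correctness and robustness of the *computational chain* under controlled
degradation — not clinical performance on real photoacoustic data.

## Numerical choices and problem sizes

* Ball structuring elements include a voxel iff its physical centre lies
  within the radius; outside-the-grid voxels impose no constraint on
  erosion/dilation (border-safe for interior structures).
* Components use 26-connectivity throughout (preserves thin diagonal
  necks); the background topology test in thinning uses the standard
  6-connectivity complement.
* The sweep crossing is linearly interpolated between bracketing radii;
  with several crossings the one nearest 0.5 wins; without a crossing the
  radius minimising the gap is returned with a flag.
* Median-volume component filtering retains ties (volume = median).
* Adaptive thresholds compute local means with an integral volume; border
  windows are clipped to the valid region.
* Default working volumes in the test and acceptance suites are
  80×96×96–96×128×128 voxels at 1 µm isotropic spacing — large enough for
  ~3 vessel trunks and a few hundred sinusoid walks, small enough that the
  whole validation chain runs on a laptop-class single core in minutes.
  The generator default (150×256×256) matches a typical cropped
  acquisition field.

## Known limitations

* Histogram matching is not content-aware (see above); volumes whose
  structure changes radically across depth should be enhanced with care or
  not at all.
* The separation is size-based; pathological small vessels with
  sinusoid-like diameters will be assigned to the sinusoid compartment.
* Skeleton-based length slightly underestimates tube length at open tube
  ends (endpoint erosion during thinning, ~2 voxels per end).
* The GLCM composite is an ordinal quality score, not a calibrated
  physical quantity; only within-set comparisons are meaningful.
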