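---
title: "Allometric leaf-area models for vine leaves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric leaf-area models for vine leaves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vineleaf)
```

## The problem

Grapevine leaves are five-lobed and deeply sinused, which defeats the
length-times-width area formulas that work for entire-margined crops. The
lamina is, however, well described by a small skeleton of measurable
elements: the midrib MR; the first- and second-order lateral veins (VL1,
VR1, VL2, VR2) with the distances DV1 and DV2 between the paired vein tips;
the four sinus-base distances DSL1/DSR1/DSL2/DSR2; and the angles α (midrib
to first-order right vein) and β (first- to second-order right vein). All
lengths are in centimetres, angles in degrees, areas in cm² except at the
size-classification boundary, where the class limits are defined in mm² and
the package converts explicitly (×100).

`vineleaf` estimates lamina area from this skeleton in two ways: a
surface-constant allometry and single-descriptor polynomial regressions.

## The surface-constant model

The allometric law is

$$\mathrm{MLA} = \mathrm{MR} \cdot \mathrm{DV} \cdot K_A,$$

with DV = DV1 (constant $K_{A1}$) or DV = DV2 ($K_{A2}$). MR·DV is the area
of the bounding parallelogram-like product of the leaf's length and an
effective width; $K_A$ is the cultivar-specific fraction of that product the
lamina actually fills. Calibration is deliberately a discrete grid search,
not a closed-form regression: for each candidate $K_A$ on a grid (default
0.50–1.50, step 0.01) we compute per-leaf MLA and two accuracy measures
against the scanned reference SLA,

* $\mathrm{ME} = \overline{\mathrm{MLA}} - \overline{\mathrm{SLA}}$, the
  signed bias of the sample means (negative = underestimate), and
* $\mathrm{RMSE} = \sqrt{\tfrac1n\sum_i(\mathrm{MLA}_i - \mathrm{SLA}_i)^2}$,
  the per-leaf error with population normalization.

The selected constant minimizes RMSE, ties broken by minimum |ME|, then by
the smaller KA. RMSE is primary because ME, a difference of means, can be
driven to zero by a constant that leaves large compensating per-leaf errors;
on the published candidate grids this rule reproduces all twelve constants,
including the two supraunitary second-order constants (1.07 and 1.08). Since
ME is defined on means and RMSE on leaves, RMSE ≥ |ME| always (Jensen), and
mean MLA and ME are exactly linear in KA while RMSE is convex with a single
minimum up to grid resolution — properties the test suite asserts on every
computed grid.

A least-squares estimate of KA ($\hat K_A = \sum p_i s_i / \sum p_i^2$ with
$p = \mathrm{MR}\cdot\mathrm{DV}$) would be continuous and nearly identical;
it is used only as an independent cross-check in tests, because the method
under study is the grid.

## Polynomial prediction models

For each descriptor $x$ the package fits ordinary least squares polynomials
$\mathrm{PLA} = b_0 + b_1 x (+\, b_2 x^2)$ of degree 1 and 2, keeps the
better by adjusted R² (the published equation set mixes linear and quadratic
forms without a stated rule, so a rule had to be chosen; adjusted R² is the
standard nesting-aware choice), discards descriptors whose overall-F p-value
is ≥ the significance threshold (default 0.05 — this is what removes the
angles α and β on realistic data, which carry no size information), and
ranks survivors by RMSE. The RMSE here uses the same divide-by-n definition
as the calibration module, so the two modules' errors are directly
comparable; the tests assert the shared definition.

The eleven published equations are carried as fixed reference constants
(`published_models()`), not refit: the per-leaf data behind them are not
public, and their printed p-values are not consistent with any plausible
sample size (p = 0.0103 at R² = 0.485 matches neither n = 6 cultivar means
nor n = 180 leaves), so refitting could not be validated. Fitting machinery
is instead validated on synthetic data with known generating coefficients.

`side_comparison()` compares homologous left/right descriptor pairs by R²
(RMSE breaks ties) and calls an overall winner by pairs won. With symmetric
noise the winner is a coin flip; a systematic left advantage appears exactly
when right-side measurements are noisier, which is how the package's
Monte-Carlo check is constructed (below).

## Leaf geometry

`build_leaf_shape()` realizes a descriptor set as a 2-D lamina: base at the
origin, midrib along +y, right side at +x, so "left" and "right" are
unambiguous in code. Vein tips sit at their measured lengths along
directions α and α+β clockwise from the midrib on the right, mirrored on the
left with angles scaled by `left_angle_factor` (1 = symmetric skeleton).
The published data give sinus-to-base distances but no directions, so sinus
bases are placed on the angular bisector between adjacent vein directions —
the neutral choice that puts each sinus between its two lobes. The outline
is the closed 10-vertex polygon base → VR2 → sinus R2 → VR1 → sinus R1 → MR
→ sinus L1 → VL1 → sinus L2 → VL2 → base. DV1/DV2 are *emergent* tip
distances of this construction, not inputs; the builder stores them back
into the shape's descriptor record.

Degenerate inputs are rejected, not repaired: a sinus distance reaching past
a flanking vein tip fails validation with the sinus named, and any outline
whose non-adjacent edges cross is rejected with the offending landmarks
named. An optional quadratic-arc smoothing (off by default; the margin shape
is unspecified in the source data, so piecewise-linear is the default) keeps
every landmark exactly on the outline by anchoring each arc to pass through
its vertex at the arc midpoint.

`polygon_area()` is the shoelace formula — the exact-area oracle.
`rasterize()` emulates a flatbed scan: a pixel is occupied when its centre
is inside the outline under the even-odd rule, implemented as a scanline
fill with the half-open vertex convention (deterministic and
orientation-free), with a one-pixel margin around the bounding box;
`pixel_area()` is occupied-count × pitch². At the default generator pitch of
0.02 cm the pixel area of a mean-sized leaf agrees with the exact area to
about 0.1%; the tests require better than 0.5% at 0.01 cm over 100 random
shapes. `quantize_ruler()` emulates the ±0.5 mm ruler by rounding lengths to
the nearest multiple of 0.05 cm, half away from zero (a 1e-9 epsilon keeps
decimal ties that are not binary-representable on the documented side);
angles, read from images rather than a ruler, are untouched.

One consequence of the straight-edged idealization: real laminas bulge
outside the vein-tip polygon, so the polygon fills only ≈0.45 of MR·DV1,
versus ≈0.9–0.97 for scanned leaves. Calibration on geometrically generated
data therefore optimizes near (or below) the default grid's lower edge —
use a wider grid (e.g. 0.30–1.50) when calibrating against `"geometric"`
reference areas. The allometric area rule, which plants a known constant,
is the right harness for validating the calibration itself.

## What the generator emulates — and what it does not

`cultivar_presets()` carries the six published cultivar summaries (30 leaves
each) verbatim, plus each cultivar's mean scanned area. Two generator
choices were genuinely open and are fixed as follows:

* **Dispersion reading.** The published "mean ± value" does not state
  whether the value is a standard error or a per-leaf SD. The default reads
  it as the standard error of the mean with n = 30 (per-leaf SD = printed ×
  √30), which yields realistic per-leaf scatter (e.g. MR SD ≈ 1.1 cm for a
  9.2 cm midrib); `dispersion = "sd"` switches to the literal-SD reading.
* **Descriptor covariance.** No covariances are published. Lengths of one
  leaf share a latent size factor with correlation `size_cor = 0.7` —
  enough that big leaves are big everywhere, as allometry requires, while
  leaving realistic independent variation; angles are size-independent.
  This single number is an assumption, not an estimate.

Draws are truncated-normal by rejection (cap 1000 tries per leaf; exceeding
the cap is an error naming the descriptor, never a silent clamp), so every
emitted leaf satisfies the feasibility invariants. Reference areas come
either from the geometry ("geometric") or from the allometric law with a
known constant and multiplicative noise of coefficient of variation `cv`
("allometric"); in the geometric path DV1/DV2 are taken from the built
shape so descriptors and area stay internally consistent, in the allometric
path they are sampled jointly with the veins.

The generator does **not** emulate: serrated margins, petioles or 3-D
curvature; any descriptor correlation beyond the single size factor;
cultivar-specific asymmetry structure (asymmetry enters only through the
user-set `left_sd`/`right_sd` noise and `left_angle_factor`). Passing tests
therefore demonstrate that the *procedures* are correct and recover known
ground truth under realistic dispersions — not that any particular vineyard
obeys the fitted constants.

## Study conditions used by the checks

The package's own acceptance checks run at the study's scale and finish in
about half a minute on one core:

* Constant recovery: n = 30 leaves, generating constant 0.95, area cv 5%,
  200 seeds; the mean selected constant must be within 0.005 of truth
  (observed bias ≈ 0.0007). Noiseless samples must recover the constant
  exactly at grid resolution.
* Raster accuracy: 100 random feasible shapes, pitch 0.01 cm, relative
  error < 0.5% (observed maximum ≈ 0.02%).
* Geometry round trip: 100 random shapes with asymmetric skeletons,
  descriptors re-measured to 1e-9.
* Left-vs-right: right-dominant measurement noise (left SD 0.1 cm, right SD
  1.0 cm — strongly dominant, as the comparison concerns direction, not
  effect size), 30 leaves, 100 seeds; the left side must win at least 90.

## Known limitations

* The published equation set and candidate grids are reference constants;
  thirteen of the sixty published grid cells do not reproduce ME = MLA −
  SLA at two decimals (ten by a 0.01 rounding artefact, three apparent
  misprints), and the exact-arithmetic checks are restricted to the
  forty-seven consistent cells.
* The surface constants and equations transfer only to cultivars of similar
  leaf typology; the package makes no attempt to generalize them.
* The polygonal lamina under-covers real leaves (previous section), so
  geometric synthetic data and real scans occupy different KA ranges.
* Angles are carried in degrees end to end; no radian interface is exposed.
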