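---
title: "Quantifying zebrafish larval tumor xenografts: methods and design"
author: "xenoquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying zebrafish larval tumor xenografts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoquant)
```

## The measurement problem

Human tumor cells labelled with a lipophilic red membrane dye (CM-DiI) and
injected into the perivitelline space of 2-dpf zebrafish larvae form a
compact graft around the yolk. A few days later, three readouts summarise
tumor behaviour in a single 2-D fluorescence micrograph:

* **proliferation** — the dye-positive area inside the yolk region;
* **invasion** — the dye-positive area inside the trunk region, where only
  disseminated cells appear;
* **migration** — the area of the polygon spanned by the peripheral tumor
  cells (the *coverage area*), divided by the dye-positive tumor area. The
  division removes the dependence on how many cells the larva received, so
  the ratio is a dimensionless dispersion score.

Two complications make naive thresholding insufficient. First, the yolk is
autofluorescent and accumulates nonspecific dye signal, so micrographs
contain small bright spots — apoptotic bodies, dye aggregates, debris — that
are *not* cells. These spots are much smaller than cells, which is the basis
of the reproducible exclusion rule implemented here: after connected-
component labeling, any object below a minimum cell area is flagged as
debris and excluded from every area and hull computation (it stays in the
object table for audit). Second, region boundaries (yolk, trunk) are drawn
by hand in practice; the package therefore takes regions of interest as
polygon input and never tries to detect anatomy automatically.

## Processing model

One larva is processed as:

1. **Threshold** the tumor channel. Default: Otsu's method computed on the
   pixels inside the union of the ROI masks, so background outside the larva
   cannot drive the threshold; a fixed intensity can be supplied instead. A
   degenerate automatic threshold (all-background or all-foreground, e.g. an
   uninjected control) falls back to a configured fixed threshold with a
   warning rather than returning silently.
2. **Label** the above-threshold pixels into connected components
   (8-connectivity by default; anti-aliased disk rims fragment under
   4-connectivity). Labeling is a compiled breadth-first search; a
   label/area conservation invariant (object areas sum to the foreground
   pixel count) is checked by the class validity method after every
   segmentation.
3. **Flag debris** by object area. The default threshold is 25% of the area
   implied by the configured expected cell diameter (16 µm → threshold
   ≈ 50 µm²), expressed in µm² so behaviour is identical across acquisition
   dialects; any threshold can be set explicitly, and the area rule is the
   only discriminator — intensity plays no role.
4. **Measure region areas** pixel-wise: non-debris foreground intersected
   with each region mask, converted to µm² through the pixel size. Yolk,
   trunk and outside pixel counts partition the foreground exactly; the
   per-object majority-region assignment table is a convenience output only
   (ties go to "outside").
5. **Coverage hull and migration index.** The "polygon through peripheral
   cells" is realised as the convex hull of the *pixel-square corners* of
   every non-debris foreground pixel in the analysis region (the yolk by
   default, matching the high-resolution migration analysis; a flag widens
   it to the whole field). Using pixel corners rather than centroids makes a
   single-cell scene well defined (its hull is the pixel square), guarantees
   that the hull contains the entire tumor pixel set, and hence guarantees
   migration index ≥ 1 with equality exactly for convex solid tumors. Hand-
   drawn polygons in practice may be concave; the convex hull is the
   reproducible choice, and the resulting index should be compared only
   across groups processed identically. An empty analysis region yields
   missing metrics (never zeros) and an `empty_tumor` status flag.

## Coordinate and boundary conventions

Rasters are indexed like R matrices; continuous geometry uses 0-based
(row, col) pixel-corner coordinates with the origin at the top-left corner,
so pixel (i, j) occupies the unit square [i−1, i] × [j−1, j] and its centre
is (i−½, j−½). A polygon covers a pixel when it contains the pixel's
centre, tested with an even-odd crossing rule whose half-open boundary
convention ("one endpoint strictly below the query row") resolves edges and
vertices consistently; because centres sit at half-integer coordinates,
polygons with non-pathological vertices never hit an ambiguous case. An
axis-aligned rectangle with corners (0,0)–(10,20) therefore rasterizes to
exactly 200 pixels. Self-intersecting polygons are rejected with a geometry
error, and yolk/trunk masks are checked for disjointness when a `RoiSet` is
built.

## The synthetic larva simulator

No public larval xenograft image set accompanies this kind of assay, so the
package ships a simulator whose scenes carry complete ground truth; every
downstream stage is validated against it.

A scene is built on a canonical larva template — an ellipse-like yolk and an
elongated tapering trunk, stored as unit-coordinate polygons and scaled to
the raster — which a user-supplied `RoiSet` overrides. The defaults encode
the study conditions the pipeline is meant for: a stereomicroscope dialect
of 1200 × 1600 pixels at 2.5 µm/pixel (a confocal 1024 × 1024 dialect is
equally supported), ~400 injected cells, cell radius 8 ± 1 µm, a few percent
of cells disseminated to the trunk, a few dozen debris spots of mean radius
3 µm (well below cell size), diffuse yolk autofluorescence at ~3% of the
16-bit range and additive Gaussian read noise (sd 500). Tests and examples
use down-scaled rasters (160 × 200 to 400 × 320 pixels) with proportionally
fewer cells so a full cohort simulates in seconds; nothing in the geometry
depends on the raster size.

Rendering and placement:

* Cells are anti-aliased filled disks: per-pixel coverage ramps linearly
  across the rim as clamp(r + ½ − d, 0, 1), so coverage ≥ ½ exactly when
  the pixel centre is within the radius — the same test that defines the
  ground-truth rasterization. On a noise-free, constant-intensity scene a
  threshold at half the peak intensity therefore reproduces the truth mask
  pixel for pixel, which the tests exploit.
* Debris spots are rendered identically to cells, with radii drawn from the
  debris distribution and intensities from the same intensity distribution:
  size is deliberately the *only* discriminator available to the filter.
* Yolk cells are placed by an isotropic Gaussian around the yolk centroid
  (sd = the dispersion parameter), rejected into the yolk polygon; trunk
  cells are uniform in the trunk; the trunk cell count is binomial in the
  trunk fraction.
* Debris is placed uniformly in the yolk under a no-contact rule: a debris
  spot never touches a cell or another debris spot (centre distance must
  exceed the radius sum plus a 2-pixel guard). Real debris can touch cells;
  the rule is a deliberate simulator simplification that keeps each debris
  spot its own connected component, making exact debris-set recovery a
  well-posed test. Consequently, passing the recovery tests says nothing
  about debris that overlaps cells in real images — such debris is absorbed
  into the cell object there, slightly inflating areas.
* Group effects are multiplicative: a cohort design scales cell count
  (proliferation), trunk fraction (invasion, clamped to 1) and placement
  sigma (migration) per group. Per-larva seeds derive from the design seed
  by a fixed affine step modulo 2³¹ − 1, so any larva can be regenerated in
  isolation and cohort output is independent of generation order; identical
  parameters and seed reproduce a scene bit for bit.

One subtlety matters when validating the scaling law (true area linear in
cell count × proliferation multiplier): the true area is a *disk union*, so
overlap makes it sublinear in the cell count, with a relative deficit of
roughly half the cell-area density. Scaling-law checks therefore use
low-density scenes (≈10 cells of 5 µm radius in the yolk), where the
overlap deficit (~1%) is comfortably below the Monte-Carlo error of the
group means; at graft-like densities the same ratio would read a few
percent low for purely geometric reasons.

What the simulator does **not** emulate: optical blur (no PSF), 3-D stacks
(real confocal data are projected to 2-D before quantification),
vasculature dynamics (the EGFP channel is decorative), uneven illumination,
larva-to-larva anatomical variation, and attrition of injected cells — the
cell count is specified directly rather than modelling survival from the
~400 injected. Passing the recovery tests therefore demonstrates
correctness of the *measurement machinery*, not robustness to every
real-world artefact; on real images the threshold and the debris cut remain
the operator's responsibility.

## Assay analytics

Relative expression uses the 2^−ΔΔCt form: ΔCt = Ct(target) −
Ct(reference) per sample, ΔΔCt subtracts the *arithmetic mean* control ΔCt
(not per-pairing), and replicate fold changes are averaged on the fold
scale. The averaging order is a documented, test-pinned choice; published
tables rarely state theirs. Knockdown efficiency is (1 − mean treated
fold) × 100, so efficiency + 100·fold ≡ 100; a mean fold above 1 returns a
negative efficiency with a warning rather than an error. CCK-8 curves are
blank-corrected per timepoint, summarised as mean ± SEM per group, and
optionally normalized to each sample's own corrected baseline (flagging
samples whose baseline is ≤ 0). No amplification-efficiency correction
(Pfaffl) and no dose–response fitting are attempted — the assays this
serves use a single fixed drug dose.

## Statistics

Group comparisons are unpaired pooled-variance Student's t-tests computed
from the closed form (Welch available by flag), with two-sided p-values,
the conventional star mapping (p < 0.05/0.01/0.001), and mean ± SEM
summaries with an n−1 variance. No multiple-testing correction is applied
by default, matching common practice for these assays; Holm adjustment can
be applied by the caller. The 2 × 2 knockdown-by-drug analysis reports the
usual uncorrected pairwise comparisons (each treatment against the double
control, and the combination against each single treatment) and,
separately, an additive-scale interaction estimate with a pooled-variance
standard error. The interaction is labelled exploratory: claims of synergy
in this assay family conventionally rest on the pairwise comparisons, and a
multiplicative (e.g. 0.6 × 0.6) effect pair is *sub-additive* on the raw
scale, so the sign of the additive interaction must be interpreted with the
measurement scale in mind.

The type-I error of the t machinery is checked by simulation (2,000 null
datasets, 10 per group, empirical rejection at α = 0.05 within binomial
3 sd), and t/p agree with the independent reference implementation in
`stats::t.test` to 10⁻¹⁰ on random data.

## Numerical and degenerate-input choices

* Foreground is `value ≥ threshold`; intensities are kept in double
  precision internally (TIFF output quantizes to the 16-bit grid).
* Component labels are assigned in raster-scan discovery order, so label
  rasters are deterministic.
* Zero pooled variance: t = 0, p = 1 when the group means agree; an error
  when they differ (the statistic is undefined).
* Zero tumor area: migration index is missing with a logged reason, never
  infinite or zero.
* Convex hulls come from `grDevices::chull` with a shoelace area; tests
  validate against a brute-force gift-wrapping oracle to 10⁻⁹ relative
  error.
* Per-larva pipeline failures become error-status rows; a cohort run never
  aborts on one larva.

## A worked demonstration

```{r demo, eval = FALSE}
demo <- runDemo(seed = 20)          # NC vs knockdown, 20 larvae per group
demo$summaries$yolk_area            # proliferation readout, mean +/- SEM
demo$summaries$migration            # dispersion readout
demo$comparisons                    # Student's t vs the NC group
demo$effect_recovered               # both directions recovered?
```

The demo simulates a control group and a knockdown group with programmed
effects (0.6× cell number, 0.6× trunk fraction, 0.5× dispersion sigma),
quantifies every larva with the default Otsu threshold and debris filter,
and reports whether the programmed directions of effect were recovered.
With the pinned seed the run is byte-reproducible, including the emitted
`metrics.csv`.

## Known limitations

* The convex hull overestimates concave coverage regions; an alpha-shape
  option is future work.
* Touching cells are quantified as area, never split into counts — the
  readouts are area-based by design, so no watershed is attempted.
* One threshold is applied per image; yolk and trunk are not thresholded
  separately.
* The debris rule is purely geometric; dim-but-large or bright-but-small
  objects that violate the size assumption will be misclassified.
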