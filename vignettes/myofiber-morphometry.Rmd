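---
title: "Methods: automated myofiber morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated myofiber morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: what is measured
and how, what the synthetic validation data emulate (and what they do
not), the numerical choices baked into the implementation, and the
design decisions that were genuinely open.

## The measurement problem

Skeletal-muscle growth after hatch is hypertrophic: fiber number is
essentially fixed and fibers grow in girth. Histomorphometry therefore
rests on per-fiber size metrics extracted from stained cross-sections:
the **lesser diameter**, the **cross-sectional area** (CSA), and the
**fiber density** (fibers per mm² of tissue). Broiler pectoral muscle is
a hard case for tools developed on rodent or human material — fiber
sizes are highly variable within one field — so per-fiber measurement at
scale, rather than a few hand-traced fibers, is the point of automating.

With Picrosirius Red Fast Green staining, myofibers appear green and
connective tissue red. The package's contract between detection and
measurement is the **label mask**: an integer image, 0 for background,
`k` for fiber `k`, each label one connected component. Any detector that
produces such a mask (including deep-learning segmenters) plugs in via
`read_label_mask()`; the built-in classical backend makes the pipeline
self-sufficient.

## Lesser diameter as minimum Feret width

"Lesser diameter" — the maximum diameter across the lesser aspect of the
fiber — is implemented as the **minimum Feret (caliper) diameter**: the
smallest distance between two parallel lines enclosing the region, over
all orientations. The rationale is classical: when a fiber is cut
obliquely its profile elongates, inflating the major axis and the area,
but the smallest caliper width stays close to the true fiber girth.

Computation is exact rotating calipers. The minimum width of a convex
polygon is attained with one caliper flush against a hull edge, so

```
min_feret = min over hull edges e of ( max over hull vertices v of dist(v, line(e)) )
```

evaluated on the convex hull of the region's boundary. Regions come out
of `labels_to_regions()` as pixel sets plus a boundary polygon traced on
the pixel-corner (half-integer) grid, treating pixels as unit squares —
so a 2×2 pixel block has polygon area exactly 4 px² and a digitized disk
of radius r measures 2r within ~1 px. The test suite checks the calipers
result against an independent brute-force oracle (projection-width sweep
at 0.01° steps). One caveat discovered while validating: a fixed-step
sweep has *first-order* angular error at V-shaped width minima, so on
sliver shapes it is not a 0.1%-grade oracle; the oracle population is
therefore fiber-like blobs, which is also the shape class the pipeline
measures.

CSA is the hole-filled pixel count divided by `px_per_um²`. Interior
unstained spots in a fiber profile are staining artifacts — a myofiber
cross-section is simply connected — hence hole filling before area;
Feret diameters use the outer hull and are unaffected by holes.

## Calibration

All metrics pass through one calibration scalar, `px_per_um` (pixels per
micrometer). The documented default is 6.6 px/µm (≈ 0.15 µm/px), the
value appropriate for stitched ×60 brightfield fields of this material.
The source protocol states the ratio without units-per-direction; we
read it as pixels-per-µm because the reciprocal reading (6.6 µm/px)
would render a 22 µm fiber about 3 px wide — unsegmentable and
inconsistent with the imagery. Calibration is metadata: it never
resamples pixels and is applied only when metrics are extracted.

## Classical segmentation backend

`segment_fibers()` re-implements the detection stage with classical
operators so that the pipeline runs without network weights:

1. **Stain score** `s = (G − R + 255)/510` on 8-bit channels: 1 for pure
   green, 0 for pure red, 0.5 for gray. Smoothed with a Gaussian of
   `smoothing_sigma_um` (default 1 µm) converted to pixels.
2. **Foreground** by Otsu's threshold on the score. Otsu is
   parameter-free, which matters because no threshold is published for
   this material.
3. **Fiber splitting** by marker-controlled watershed on the Euclidean
   distance transform of the foreground. Markers are distance-map maxima
   after **h-maxima suppression** at depth `h_maxima_um` (default 2 µm):
   maxima shallower than h merge into their neighbour basin, which is
   what prevents one fiber from splitting into several. (EBImage's
   watershed `tolerance` implements exactly this suppression.)

Defaults, units, and why:

| parameter | default | meaning |
|---|---|---|
| `smoothing_sigma_um` | 1 µm | noise suppression below fiber scale |
| `h_maxima_um` | 2 µm | merge depth ≈ endomysium half-scale; guards against over-segmentation |
| `min_area_um2` | 50 µm² | drops debris below ~8 µm equivalent diameter, under the smallest populated histogram bin |
| `exclude_border` | TRUE | edge-clipped fibers bias lesser diameter downward |
| `connectivity` | 8 | standard for blob labels |

`filter_labels()` applies the last two and renumbers survivors 1..K; it
is idempotent, so QC can be applied defensively. Whether the original
workflow excluded edge fibers or applied a size floor is not stated in
the protocol; both are explicit, documented switches here
(`--include-border`, `--min-area-um2 0` restore the permissive reading).

## Fiber density

Density is fibers per mm², "normalized to total section area". Section
area is read as *tissue* area, not raw image area: the stained support
(stain score > 0.05 or any fiber label), morphologically closed with a
5 µm disc so the thin endomysium between fibers counts as tissue. Since
the reading is not settled by the protocol, the summary reports both
denominators (`fibers_per_mm2` on tissue area — the default — and
`fibers_per_mm2_image` on image area); when no image accompanies a mask,
tissue support falls back to the closed union of the labels.

## Synthetic sections with exact ground truth

No stained images are redistributable with this package, so validation
runs on synthetic SRFG-like sections (`generate_section()`) built to the
morphology reported for 14-day-old broiler pectoral muscle: **mean
lesser diameter 22.8 µm, CV 32%**, thin (2 µm default) endomysium — the
generator's defaults *are* these study conditions.

Construction:

1. Fiber centers on a jittered grid (`jitter` = 0.5 by default; 0 gives
   a crystal, 1 near-Poisson disorder without the pathological tiny
   cells of a true Poisson process). Grid spacing is the expected fiber
   footprint `(mean + border) × (1 + CV)` — the inflation leaves room
   for upper-tail fibers.
2. Per-fiber diameter draws from a **zero-truncated normal**
   (mean 22.8, sd = CV×mean). A lognormal was considered and rejected:
   at exactly these parameters its mass in the [15,20) and [20,25) µm
   bins is identical to four decimal places (its mode is 19.7 µm), so
   the modal 5 µm bin of the synthetic histogram would be a coin flip,
   whereas real fiber-diameter histograms of this material are
   near-Gaussian with a clear 20–25 µm mode. Truncation at zero sits
   3.1σ below the mean and is negligible; positivity is preserved,
   which was the only argument for the lognormal.
3. A **power (Laguerre) diagram** over the centers, with generator
   weights `(d_k/2)²` from the draws: a Voronoi-type tessellation in
   which cells expand with their fiber's drawn size, so large draws get
   the space they need instead of being clipped by an unweighted cell.
   Power cells are convex, which step 4 relies on.
4. **Erosion to size**: each cell shrinks to its drawn diameter using
   the distance map to the tessellation edges. Eroding a convex cell by
   a disc of radius e reduces its minimum caliper width by exactly 2e,
   so the erosion is `(c_k − d_k)/2` with `c_k` the cell's measured
   minimum Feret width, floored at `border/2 + 0.5 px` — the floor is
   what guarantees every pair of fibers is separated by at least
   `border_width_um` of background. A 0.875 px relaxation on the
   erosion threshold compensates two digitization effects (pixel
   centers sit half a pixel inside the crack boundary; thresholding a
   quantized distance map rounds the kept band inward), measured as a
   −1.75 px realized-vs-drawn width offset in an instrumented run.
5. **Rendering**: green-dominant fiber interiors, red-dominant
   background, ±5% multiplicative uniform noise — mild on purpose, so
   the classical backend's quality bar is meaningful but stable across
   seeds. Labels are renumbered 1..N in raster order of centroid;
   edge-clipped fibers are labeled (not suppressed) so border-exclusion
   QC is exercised by tests.

Ground truth (`true_metrics()`) is measured from the mask by the same
geometry engine as the pipeline, so generator and pipeline cannot drift
apart silently.

**What the synthetic sections do not emulate**: staining gradients and
batch variation, out-of-focus and stitching seams, fiber-shape
irregularity beyond convex polygons, abnormal morphologies (wooden
breast, white striping), nuclei and capillaries. Passing the synthetic
suite therefore demonstrates the measurement chain is correct on
clean, known geometry — it does not certify detection performance on
difficult real-world staining, which is exactly why external label
masks are a first-class input.

Problem sizes used by the test suite (chosen as desk-scale validation
runs): a ~40-fiber and a ~140-fiber section for invariants and
segmentation checks, and one ~1,200-fiber section (2200² px at
2 px/µm) for parameter recovery — mean recovered within 5%, CV within
15% relative, modal bin [20,25) µm, ≥90% of fibers matched one-to-one
against ground truth at IoU ≥ 0.5.

## Method-agreement and group statistics

The agreement metrics follow the published definitions exactly:
`CV = SD/mean × 100` (sample SD), `accuracy = (1 − |test − ref|/ref) ×
100` — note the *reference* (manual) denominator; the metric is
asymmetric and the report labels direction — and `productivity = data
sets / hours`, where a fiber measured for diameter and area counts as
two data sets and a diameter-only (manual) fiber as one; this counting
rule is the only one consistent with the published throughput figures
(2 × 15,881 / 1.4 h ≈ 22,687; 17,333 / 54 h ≈ 321). The published
84-image productivity (26,279) is not consistent with its own inputs
(2 × 59,128 / 4.2 ≈ 28,156); the package reproduces the self-consistent
27-image arithmetic and leaves the discrepancy noted.

`compare_groups()` runs, per metric, one-way ANOVA across the two groups
followed by a two-sample Student t test with pooled variance (the
published analysis names Student's, not Welch's, t). With two groups
F = t² and the p-values coincide — kept as a cross-check invariant.
Units of analysis: diameter and area are tested at the **fiber level**;
the published SEMs (±0.03–0.06 µm on ~20k fibers) are only attainable
with fiber-level n, so that is the reading adopted. Fibers within an
image are not independent — the pseudoreplication caveat is printed in
the report — and density is tested at the **image level**, since one
density value exists per image. No multiple-testing correction is
applied across the three metrics, matching the published analysis.

## Numerical conventions and degenerate inputs

- SEM uses sample SD (n−1); n = 1 gives SEM 0; empty sections give
  `n_fibers = 0` with NA means rather than an error.
- Collinear "polygons" get lesser diameter 0 with a warning, not an
  error; zero-mean CV and zero-reference accuracy are validation errors.
- Diameter bins are left-closed, right-open (`[0,5), [5,10), …`), so a
  diameter of exactly 5.0 falls in [5,10); percentages sum to 100 within
  1e-9.
- 8-bit images are read verbatim; deeper or float rasters are min–max
  scaled per channel to 0..255 at ingestion only.
- All randomness (generator, CLI `simulate`) is seeded; identical
  parameters including the seed produce bit-identical images, masks and
  records, and the caller's RNG stream is left untouched.
- Tabular output is UTF-8 CSV with 6-decimal floats. An XLSX writer is
  deliberately not provided; the CSV schema is the canonical interchange
  and opens in any spreadsheet.

## Known limitations

- The classical backend assumes the green-vs-red stain contrast; it is
  not a general instance segmenter, and on weakly stained or damaged
  tissue an external detector feeding `read_label_mask()` is the right
  tool.
- Fiber-level p-values inherit pseudoreplication; a nested or
  mixed-effects analysis is out of scope by design.
- The synthetic generator constrains mean and CV of the diameter
  distribution but not higher moments; skewness beyond the truncated
  normal's is not modeled.
- Labels above 65,535 cannot be written to 16-bit mask files (no
  practical section approaches this).
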