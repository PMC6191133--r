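---
title: "Measuring capped brood and honey from frame photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring capped brood and honey from frame photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CombQuant)
```

## The measurement problem

Colony assessments score each side of each hive frame for the surface of
capped brood (sealed pupae) and capped honey (sealed stores). Fully
manual tracing of region outlines is precise but takes on the order of
ten minutes per frame side; trained-observer visual scoring is fast but
coarse. CombQuant splits the work by reliability: a detector finds
**uncapped** cells automatically — the one cell class with unambiguous
visual structure, a dark near-circular lumen inside brighter wax walls —
and a human supplies the two judgements vision cannot make safely, namely
which contiguous regions are capped brood versus capped honey, and where
the inner frame edges are. The capped area of a region is then its
polygon area minus one small disc per detected uncapped cell inside it.

The key assumption is geometric: comb cells form a hexagonal lattice of
roughly constant pitch within a photograph, so a single per-photo spacing
estimate converts "number of uncapped cells inside the outline" into an
uncapped *area* to subtract.

## Detection model

Detection operates on CIELAB *L\** (sRGB primaries, D65 white point,
*L\** in [0, 100]). Lightness is computed per pixel via linearisation of
the sRGB transfer curve, the Rec. 709 luminance weights normalised to the
white point, and the CIELAB cube-root transform. Perceptual lightness is
the channel on which lumens are consistently the darkest structures
regardless of camera or flash.

The Hough gradient transform then:

1. computes 3×3 Sobel derivatives on *L\** rescaled to the 8-bit range,
   and takes pixels with L1 gradient magnitude `|Gx| + |Gy|` at or above
   the **edge threshold** as edge pixels. This is a single-threshold
   variant of the Canny front end (the usual L1 convention for its high
   threshold); hysteresis adds nothing here because lumen rims are
   high-contrast closed curves, and omitting it keeps the detector a pure
   function of two documented thresholds;
2. lets every edge pixel vote at `centre = pixel ± r·(unit gradient)` for
   each candidate radius `r` in 1 px steps — both directions, so the
   polarity of the rim does not matter;
3. keeps accumulator local maxima with at least the **accumulator
   threshold** votes, thinned greedily by vote count under a minimum
   centre separation (ties break on scan order, so detection is exactly
   deterministic);
4. refines each surviving centre and radius with an algebraic (Kasa)
   circle fit to the edge pixels within 1.5 px of the winning
   distance-histogram ring, iterated twice and rejected if the fit
   wanders more than 2 px. The fit averages over the ~30–40 rim pixels of
   a lumen and brings centre error down to about half a pixel, which
   matters for the spacing estimate below.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `EDGE_THRESHOLD` | 200 | 8-bit gradient | edge-pixel cut; the standard operating value |
| `ACC_THRESHOLD` | 20 | votes | circle sensitivity; lower ⇒ more circles |
| `THRESHOLD_INC` | 2 | votes | operator sensitivity step (`stepSensitivity()`) |
| `CELL_INFLATE` | 1.0 | – | multiplicative calibration of the subtraction radius |
| `RADIUS_FRACTION` | 0.5 | – | spacing → base radius conversion |
| `MIN_RADIUS`, `MAX_RADIUS` | 0.25·pitch, 0.75·pitch | px | Hough radius search bounds |
| `MIN_DIST` | 0.6·pitch | px | minimum accepted centre separation |
| `EXPECTED_PITCH` | width/80 | px | prior pitch used for the three defaults above |

On a hexagonal lattice the nearest-neighbour distance between cell
centres is the **pitch**, i.e. approximately one cell *diameter*.
`RADIUS_FRACTION = 0.5` therefore treats the median nearest-neighbour
spacing as a diameter when forming the subtraction radius; setting it to
1.0 reproduces the alternative convention of using the spacing directly
as a radius. With the default, the subtracted discs for a fully uncapped
patch cover π/(2√3) ≈ 91 % of its area (the disc-packing density of the
lattice) rather than overlapping threefold; residual bias is exactly what
`CELL_INFLATE` exists to absorb, calibrated once per apiary against a few
hand-traced photos. For the synthetic scenes the same calibration is done
analytically: `fixtureDetectionParams()` sets
`CELL_INFLATE = 2·lumen radius / pitch`, making the effective radius
equal the true lumen radius.

The accumulator threshold is exposed exactly as the operator experiences
it: an initial value of 20 stepped by 2 via
`stepSensitivity(params, "increase_detections" | "decrease_detections")`,
clamped at 1 with a warning. The initial value and the step are
independent parameters, so a dataset that consistently needs a different
starting sensitivity can set `ACC_THRESHOLD` directly in the config.

## Spacing estimation and its small bias

`medianNeighbourSpacing()` is the median over circles of the distance to
the closest other circle (even counts average the two central values).
It is translation- and rotation-invariant and scale-equivariant, and the
median makes it robust to the handful of spurious or missed detections a
real photo produces.

One property is worth stating because the test suite quantifies it: under
independent per-cell centre jitter with standard deviation σ, each
circle's nearest neighbour is the *minimum* of six approximately equal
distances, so the estimate is biased below the true pitch by roughly
1.3·σ√2 plus the detector's localisation error. At the synthetic
defaults (σ = 0.4 px on an 18 px pitch, ~0.5 px localisation error) the
estimate lands near 17.3 px, about 4 % low. This is a property of the
estimator's definition, kept deliberately; the calibration factor absorbs
it in practice.

## Quantification conventions

* **Shoelace area** for polygons; vertex order irrelevant;
  self-intersecting outlines are rejected as invalid geometry rather than
  silently measured.
* **Boundary-inclusive ray casting** for point-in-polygon: a centre
  exactly on the outline counts as inside, so abutting outlines do not
  drop cells.
* **Membership by centre, no disc clipping.** A cell whose centre is
  inside the outline subtracts its full disc even if the disc crosses the
  border; a cell just outside subtracts nothing. The two errors cancel to
  first order along a straight border, and the closed-form subtraction
  keeps every measurement auditable from the detections CSV alone. The
  residual is a known edge bias of order (perimeter × r) in the worst
  case.
* **Clamping at zero.** Over-subtraction (tiny outline, many cells) is
  clamped to 0; the raw negative value is reported via a message so batch
  logs keep the evidence.
* **Physical scaling** multiplies by `inner_frame_cm2 /`
  (pixel area of the inner-corner quadrilateral). Photographs are assumed
  perpendicular to the comb face, as the photography protocol requires,
  so no homography rectification is applied; a rectification pre-pass
  would slot in before `toLuminance()` if oblique photos ever had to be
  processed. The physical inner-frame area is a config value — frame
  models differ, so no constant is hard-coded.
* Overlapping outlines of different labels are accepted but flagged,
  since the per-label areas then no longer partition the comb face; the
  "sum of capped areas ≤ inner area" invariant is asserted only for
  disjoint outlines.

## The synthetic scene generator

`generateCombImage()` renders what the detector actually keys on:

* a flat-row hexagonal lattice (row spacing pitch·√3/2, odd rows offset
  by pitch/2) with per-cell Gaussian centre jitter;
* uncapped cells as lumen-radius discs at L\* 20 ringed by 2 px walls at
  L\* 72; capped regions as per-pixel Gaussian texture around L\* 52
  (σ = 5); bare wall elsewhere;
* a linear illumination ramp (± 8 L\* units across the image) and
  Gaussian sensor noise (σ = 1.5 L\*), emulating the with/without-flash
  variation between field cameras;
* greyscale lifted to 8-bit sRGB by inverting the lightness transform,
  so `toLuminance()` recovers the intended L\* values to within
  quantisation.

All randomness (jitter, texture, noise) comes from one private stream
seeded by the scene's `seed`; the global RNG state is untouched and two
renders with the same spec are bit-identical. The layout is fixed per
scene; seeds vary only the realizations.

The canonical scene (`defaultFixture()`) is 1200×800 px at pitch 18 px:
one capped-brood and one capped-honey rectangle (each perforated by three
small uncapped "holes", the missed or emerged cells that make the
subtraction non-trivial) and one large open band — 502 uncapped cells in
total. Ground truth is analytic: every jittered uncapped centre, and per
label the polygon area minus one lumen disc per contained uncapped
centre, so conservation (truth + subtracted lumens = gross area) holds
exactly by construction.

What the generator does **not** emulate: bees and debris occluding cells,
specular highlights on fresh cappings, irregular natural (foundationless)
comb, perspective distortion, chromatic content (scenes are neutral
grey). Passing the synthetic suite therefore demonstrates the geometry
and the detector's contrast logic, not robustness to occlusion or colour
casts — on real photos those remain the operator's responsibility via the
sensitivity loop and the outline placement.

Scene defaults were chosen once as representative of flash photographs of
foundation-built comb: jitter σ = 0.4 px (≈ 0.12 mm at this resolution —
embossed foundation keeps cells very regular), and L\* levels measured
off typical published comb photographs to the nearest 5 units.

## Exact signed-rank test

Method-comparison samples in this setting are tiny (a handful of
observers or frames), far below any asymptotic regime, so the paired
Wilcoxon test is computed exactly: differences `b − a`, zeros dropped
(the original convention), midranks on `|d|`, `V =` sum of ranks of
positive differences, and the null distribution from all `2^n` equally
likely sign assignments on the realized rank multiset. Up to `n = 15` the
assignments are enumerated explicitly; beyond that an integer convolution
over doubled midranks produces the identical distribution (doubling makes
midranks integral, so no floating-point tie matching is needed anywhere).
The two-sided p doubles the smaller tail, capped at 1 — six pairs all in
one direction give `V = 21`, `p = 2/64 = 0.03125`. `n` is capped at 25,
where exactness stops being cheap and any standard implementation's
approximation becomes adequate.

Pearson agreement between two methods (`agreementReport()`) is routine
and delegates to `stats::cor.test`, reporting `n`, `r`, the t transform
and the mean difference.

## Numerical and degenerate-input choices

* Fewer than two detections: spacing and effective radius are `NA` — a
  flagged "unavailable", not an error — and quantification subtracts
  nothing.
* Accumulator plateaus: the local-maximum test is strict against
  already-scanned neighbours, so a flat peak yields exactly one centre.
* The Kasa refinement requires ≥ 6 supporting pixels and a positive
  fitted radius inside the search bounds; otherwise the accumulator
  centroid stands.
* Polygon validity (simplicity) is checked by pairwise segment
  intersection in O(n²) — outlines have tens of vertices, so clarity wins
  over sweep-line asymptotics.
* All-zero paired differences raise a degenerate-sample error rather than
  returning a vacuous p-value.

## Problem sizes in the shipped tests

The suite runs the five canonical 1200×800 scenes (seeds 0–4; each is
rendered and detected once and shared across test files), plus reduced
400–420 px scenes for the CLI and property tests, 100 random convex
polygons against a fan-triangulation oracle, 500 random points against a
winding-number oracle, and 50 random signed-rank samples (n ≤ 10) against
brute-force sign enumeration. The full suite completes in about a minute
on one CPU.

## Known limitations

* Capped/uncapped is the only automated distinction; brood versus honey
  is operator judgement by design.
* The area subtraction uses circles, not hexagons; the difference is
  folded into `CELL_INFLATE`.
* The spacing estimator's jitter bias (above) means `RADIUS_FRACTION`
  alone never yields an unbiased area on irregular comb — calibration is
  part of the method, not an optional extra.
* Detection assumes lumens are the locally darkest circular structures;
  heavily propolised or pollen-filled open cells can fall below the edge
  threshold and are then uncounted (they are also not "empty" in the
  stores sense, so the sign of the resulting error is context-dependent).
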