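---
title: "Measuring radiographic hip congruency: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring radiographic hip congruency: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcindex)
```

## The measurement problem

Screening for canine hip dysplasia (HD) relies on ventrodorsal
hip-extended (VDHE) radiographs scored into the five FCI grades A–E.
Two of the main criteria — the Norberg angle and the degree of hip
congruency — differ sharply in character: the angle is a number, while
congruency is traditionally judged by eye, which is a known source of
inter-observer disagreement.

The **Hip Congruency Index (HCI)** turns congruency into a number. An
examiner outlines two structures on the radiograph with a polygon
annotation tool:

* the projected acetabular coverage area (AA), traced along the margo
  acetabuli, and
* the proximal femur, whose head overlaps the acetabular outline.

The index is the fraction of the acetabular coverage area occupied by
the femoral head,

$$\mathrm{HCI} = \frac{\mathrm{AAOFH}}{\mathrm{AA}},$$

where AAOFH is the area of overlap between the two polygons. A congruent
hip leaves little acetabular free space, so HCI is high (≈ 0.74 on
average for grade-A hips); subluxation increases the free space and
drives HCI toward 0 at dislocation. Because HCI is a ratio of areas
measured on one projection, it cancels magnification, which makes values
comparable across dogs and imaging setups. HCI = 1 is unattainable in
practice: the radiolucent cartilage space, the non-circular fovea and
the femoral neck all keep some acetabular area uncovered.

The **Norberg angle** is measured at a femoral head center, between the
line to the contralateral femoral head center and the line to the
cranial effective acetabular rim; this package treats it as an unsigned
magnitude in [0°, 180°], since clinical use only refers to magnitudes
(~105° and above being typical of normal hips).

All computation here operates on annotation *coordinates* (continuous
pixels, origin top-left, y increasing downward, no half-pixel offset);
no image pixels are ever read.

## Geometry kernel

Polygon areas use the shoelace formula; the reported area is always the
absolute value of the signed sum, so vertex orientation never matters.

AAOFH requires the intersection of two arbitrary *simple* polygons —
acetabular outlines are crescent-like, so convex clipping is not an
option. The kernel implements a Greiner–Hormann-style traversal: edge
crossings are found in compiled code, each boundary is split into arcs
between consecutive crossings, arcs interior to the other polygon are
kept, and kept arcs are stitched into output rings. Three numerical
policies matter:

* **Snapping.** Coordinates are snapped to a 10⁻⁷-pixel grid before
  clipping. Annotation coordinates are integer-ish pixels, so snapping
  cannot change an area meaningfully, but it makes exact degeneracies
  (coincident vertices, collinear overlapping edges) detectable.
* **Perturbation instead of case analysis.** If the overlay detects any
  degeneracy (a crossing at a vertex, a vertex on an edge, collinear
  overlap), the second polygon is translated by a deterministic
  sub-snap offset (10⁻⁹ × coordinate scale, direction cycling through a
  golden-angle sequence) and the overlay is retried. The induced area
  error is bounded by perimeter × offset — orders of magnitude below
  any tolerance used here — and the retry sequence is deterministic, so
  identical inputs always give identical results. A consequence chosen
  deliberately: polygons that touch only along their boundaries have an
  empty intersection.
* **Validation, not repair.** Self-intersecting input polygons are
  rejected. Silently "fixing" a figure-eight outline would change the
  measured area unpredictably; the examiner should re-draw instead.

Two independent oracles guard this kernel: the closed-form two-circle
lens area, and a midpoint-rasterization oracle for arbitrary implicit
regions. The test suite holds discretized-circle intersections to the
closed form (< 1% at 512 vertices, ~4×10⁻⁵ relative at 2048) and the
clipping route to the grid oracle on the synthetic cup model (< 0.5%).

One interaction is worth recording: the snap grid is *absolute*
(10⁻⁷ px), so at sub-pixel coordinate scales the snapping noise can
exceed 10⁻⁹ relative. The scale-invariance guarantees are therefore
stated — and tested — at realistic pixel scales (coordinates of order
10²–10³), where snap-induced error is ≈ 10⁻¹⁰ relative.

## The synthetic cohort: what it emulates, and what it does not

Real per-grade HCI distributions come from 400 scored radiographs and
cannot be reproduced at desk scale. The generator instead provides a
*controlled* world with known ground truth:

* **Cup model.** The acetabular coverage region is a disc of radius
  *R* cut by a chord: the part of the disc with lateral coordinate
  ≤ R·cos(θ), where θ is the *opening half-angle*. θ = 90° gives a
  half-disc (the one configuration with a trivial analytic check:
  a concentric head of radius *r* gives HCI = r²/R² exactly); the
  default θ = 70° closes the cup slightly around the head, which is
  closer to the projected dorsal coverage of a real acetabulum. The
  original annotation protocol does not pin down where the acetabular
  outline begins and ends, so this is parameterized, not fixed.
* **Subluxation axis.** The femoral head (disc of radius *r*, default
  r/R = 0.9 mirroring the analytic example) is displaced purely
  laterally by *d*. On the VDHE projection the relevant structures lie
  approximately in one plane, and lateral displacement is the dominant
  radiographic expression of subluxation; rotation and version are
  deliberately out of scope. True HCI is strictly decreasing in *d*,
  which the tests verify by oracle sweep.
* **Ground truth.** `make_hip()` computes true HCI with the grid oracle
  at ≥ 2000 cells per axis — never with the polygon-clipping path that
  the measurements use — so measurement error and generation error stay
  independent.
* **Grades.** Displacement fractions d/R are drawn per grade from
  normal distributions with means A 0.05, B 0.15, C 0.25, D 0.40,
  E 0.60 (SD 0.05, truncated at 0). These defaults produce strictly
  ordered mean HCIs A > B > C > D > E, the qualitative signature of the
  real per-grade table; they are configuration, not constants. Default
  counts (dogs per grade 60/78/34/19/9, two hips each) mirror the main
  study's per-grade hip counts.
* **Examiner noise.** Each hip is re-annotated once per examiner ×
  session with independent isotropic Gaussian jitter on every vertex
  (default SD 1 px — no quantitative noise magnitude is published, so
  this is a package choice, exposed in the configuration). Jittered
  polygons that self-intersect are redrawn (bounded retries).
  Note that pixel jitter does not scale with the anatomy, so the
  cohort-level scale-invariance property (doubling `pixel_scale`
  multiplies areas by 4 and leaves HCI unchanged to 10⁻⁶) holds for the
  noise-free geometry and is tested with `jitter_sd = 0`.
* **Reproducibility.** One global stream keyed by the cohort seed draws
  a sub-seed per dog; regenerating any subset of dogs reproduces them
  exactly.

A green synthetic test therefore establishes that the *machinery* —
geometry, I/O, statistics, pipeline — behaves correctly on shapes whose
truth is known. It does not establish anything about biological
variation the model omits: irregular margo acetabuli outlines,
osteophytes and remodeling (which bias HCI upward in severe
osteoarthritis), breed and positioning effects.

## Statistical battery

The reliability design replicates measurements across two sessions and
two examiners and analyzes hips (not dogs) as units:

* **Paired t-test** on duplicate series; 95% CI of the mean difference
  uses the t quantile.
* **Bland–Altman.** Limits of agreement are mean ± 1.96 SD with the
  constant 1.96 *exactly* — reproducing the published intervals requires
  not substituting a t quantile here, while the CI of the mean requires
  using one. Both conventions live side by side on purpose.
* **ICC(3,1)** — two-way mixed, single measure, *consistency* — from
  the two-way ANOVA decomposition, `(MS_R − MS_E)/(MS_R + (k−1) MS_E)`,
  with the F-bound confidence interval and the `MS_R/MS_E` F-test
  p-value (the natural default; the source does not state its p-value
  construction). The consistency form ignores fixed rater shifts, which
  is the intended behavior when a systematic offset between examiners
  is assessed separately by the paired t-test. Absolute-agreement
  ICC(2,1) is intentionally not provided.
* **Interpretation bands** (random/poor/moderate/good/excellent/
  perfect) use inclusive-lower, exclusive-upper edges; the verbal
  banding in the source is ambiguous exactly at 0.5/0.75/0.9, so the
  choice is documented rather than implicit. Adequate reliability means
  the *lower* 95% ICC bound strictly exceeds 0.75.
* **Welch's ANOVA** and **Games–Howell** compare per-grade means
  without assuming equal variances (the real per-grade SDs range from
  0.044 to 0.122, so homoscedastic ANOVA would be wrong). Games–Howell
  uses the studentized range distribution via R's `ptukey`, validated
  against published q-table entries to 10⁻⁴ and against the exact
  k = 2 identity with Welch's t-test; the post hoc runs
  unconditionally, with no overall-ANOVA gate.
* **Assumption checks** (Shapiro–Wilk per group; Levene's test with
  *mean* centering, the classic form and the default of the software
  used in the source study) are reported but never used to switch
  methods.

Degenerate inputs resolve explicitly rather than accidentally:
zero-variance differences flag the t-test as degenerate (CI collapses
to a point), a constant ratings matrix gives ICC = 1 with CI [1, 1],
zero-variance groups are an error for variance-based tests, and groups
with n < 3 skip the normality test with a warning.

## Tunable parameters at a glance

| parameter | unit | default | why |
|---|---|---|---|
| `acetabular_radius` R | px | 100 | typical large-breed head radius at standard film scale |
| `femoral_radius` r | px | 90 | r/R = 0.9, the analytic reference configuration |
| `opening_halfangle` θ | degrees | 70 | cup closes moderately around the head; 90 = analytic half-disc |
| `n_vertices` | count | 128 | annotation-like discretization; ≥ 64 enforced |
| `grade_displacement_mean` | d/R | 0.05–0.60 | produces ordered grade means |
| `grade_displacement_sd` | d/R | 0.05 | within-grade biological spread |
| `jitter_sd` | px | 1 | examiner noise; no published magnitude |
| `truth_resolution` | cells/axis | 2000 | grid-oracle accuracy ≈ 0.4% of cup area |
| `alpha` | — | 0.05 | two-sided tests throughout |

## Known limitations

* The intersection of two simply connected polygons can, in contrived
  configurations, be multiply connected; hole boundaries are returned
  as clockwise rings and subtract correctly from areas, but
  `polygon_intersection()`'s "disjoint simple pieces" reading assumes
  the realistic hole-free case.
* The generator cannot emulate osteoarthritic remodeling, which in real
  severe-HD hips *raises* HCI; conclusions about grade E behavior rest
  on geometry only.
* Edges are straight segments; if the original annotation tool
  interpolated splines, areas differ at the discretization level.
* LabelMe support covers the `shapes[].label/points/shape_type` subset
  with a fixed label vocabulary (`acetabulum_L/R`, `femoral_head_L/R`,
  `fhc_L/R`, `rim_L/R`); this is the package's documented protocol, not
  an upstream standard.
* Confidence intervals for the limits of agreement themselves are not
  provided, and Bland–Altman is limited to two series (no
  repeated-measures extension).
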