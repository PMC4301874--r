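---
title: "Methods: trichrome histomorphometry, CNF scoring and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trichrome histomorphometry, CNF scoring and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, how they were resolved, and what a green test
does and does not establish.

## The measurement model

Masson's trichrome renders muscle cytoplasm red, collagen blue and
unstained regions (background, vessel lumina) near-white. The collagen
burden of a micrograph is quantified by a colour-partition chain:

1. **Lab transform.** The 8-bit sRGB image is decoded (IEC 61966-2-1 gamma
   expansion), linearly transformed to XYZ and expressed in CIE L\*a\*b\*
   under D65 / 2°. Lightness (L\*) and chroma (a\*, b\*) are thereby
   separated: the red/blue distinction lives almost entirely in (a\*, b\*),
   while "white" is a statement about L\* alone. The white point is taken
   as the image of RGB (1, 1, 1) under the conversion matrix so that pure
   white maps to exactly (100, 0, 0); this differs from the nominal D65
   tristimulus values only in the seventh decimal.
2. **k-means, k = 2, on (a\*, b\*).** Every pixel participates. k is not a
   free parameter: the downstream contract is a red/blue partition.
   Initialisation is k-means++ with `kmeans_restarts = 5` starts (best
   within-cluster sum of squares wins), a fixed `kmeans_seed = 0`, and
   Lloyd iterations run to their exact fixed point (assignment unchanged),
   with `kmeans_tol = 1e-6` on relative inertia as a secondary stop. The
   fixed-point stop makes the result invariant under pixel-order
   permutation. If all pixels share one chroma the model is flagged
   degenerate and the whole image takes the single centroid's class.
3. **Cluster → class rule.** Nothing in the chain names the clusters, so a
   rule is required: the centroid with the smaller b\* (blue–yellow axis)
   is *blue* (collagen); an exact b\* tie is broken by a\* — the larger a\*
   (redder) centroid is *red*. For a degenerate single centroid, blue iff
   its b\* < 0.
4. **Uniform lightness mask.** A pixel is white iff L\* > 85. The value 85
   masks near-white background without swallowing pale collagen
   (collagen's default L\* here is 60); it is a configuration default, not
   a recovered constant, and every measurement records the configuration
   used. The same threshold must be applied to all images of a run. The
   mask is applied *after* clustering, as an override of the cluster
   label; clustering the non-white pixels only is available as
   `mask_before_cluster = TRUE` but is not the default, matching the
   narrative order cluster → mask → close.
5. **Morphological closing.** Dilation then erosion with a rasterised disk
   of radius 3 px (lattice offsets with dy² + dx² ≤ 9), applied
   independently to the red and then the blue region: gaps of radius < 3
   px fill; a hole of radius ≥ 3 survives. Closing two regions
   independently can claim the same pixel twice; such pixels keep their
   pre-closing label, on the grounds that closing should fill uncertainty,
   not reassign confidently labelled pixels. Pixels claimed by neither
   stay white.
6. **Percent collagen.** `100 · blue_px / (H · W)` — the denominator is
   the *entire* image, white included, taken literally. This makes the
   statistic depend on tissue coverage of the frame; a
   `denominator = "tissue"` option (total − white) is provided explicitly
   as the non-default alternative.

### What the green recovery test establishes

On synthetic sections the chain recovers the true collagen fraction with a
mean absolute error of ≈ 1.1 percentage points at 1024² px and preserves
the rank order of fraction levels 2–20% in every tested seed. The
dominant error term is not noise but the nuclei: dark nuclei have negative
b\* chroma and join the blue cluster, so measured blue ≈ collagen +
nuclear area (≈ 1% of the frame at defaults, and proportionally more at
small image sizes where the fixed 4 px nucleus radius looms larger).
Against the sum collagen + nuclei the agreement is within ~0.2 points.
This mirrors the real assay, where haematoxylin-dark nuclei are also
swept into the non-red class; rank comparisons between groups are
unaffected because the offset is common to all levels.

## The synthetic tissue generator

No public micrographs accompany the analysis this package operationalises,
so validation rests on a simulator whose ground truth is exact by
construction. It is a stated world, not a tuning knob: its defaults were
fixed once, before the tests were run.

* **Geometry.** Fiber seeds are drawn on a jittered grid inside a central
  tissue rectangle occupying (1 − `background_fraction`) of the frame
  (aspect preserved; the rectangle is the simplest shape whose inward
  offset stays exact under the half-plane representation). The Voronoi
  cell of each seed is the intersection of bisector half-planes, hence
  convex. The endomysial collagen band is the set of tissue pixels whose
  *margin* — distance to the nearest Voronoi bisector or tissue edge — is
  below a band width `w`; fiber polygons are the same half-planes offset
  inward by `w`, so raster, polygons and nuclei are mutually consistent.
* **Band-width solver.** The margin field is precomputed per pixel, so the
  collagen pixel count is a monotone function of `w`; 60 bisection steps
  solve it. Exact ties in the margin (whole rows of the tissue edge share
  one rectangle distance) would quantise the achievable count, so a
  deterministic sub-pixel jitter (≤ 1e-4 px, a fixed integer hash of the
  pixel index — no RNG involved) breaks ties; the achieved fraction is
  then within ±0.005 of target for targets in [0.01, 0.30], and an
  infeasible request fails with the achievable range.
* **Nuclei.** One per retained fiber (fibers whose polygon is too small to
  host a verifiable nucleus are dropped). With probability `cnf_rate` the
  nucleus is placed deep (boundary distance > 0.25 · √(area/π) + 0.5 px),
  otherwise in the peripheral band; every placement is verified against
  the *exact* centrality predicate used by the CNF module, so at rates 0
  and 1 predicate and ground truth agree without exception. The painted
  nucleus disk (radius 4 px) only overwrites muscle pixels of its own
  fiber, leaving the collagen count untouched.
* **Colour.** Class-mean Lab colours — muscle (55, 45, 15), collagen
  (60, 10, −35), nucleus (25, 15, −20), background (97, 0, 0) — chosen for
  trichrome-like appearance with clear red/blue separation in (a\*, b\*);
  independent Gaussian noise (SD 5 per Lab channel) is added before
  conversion to sRGB with gamut clipping and 8-bit quantisation. This is
  deliberately simpler than camera noise.
* **Determinism.** Identical spec (seed included) gives bit-identical
  images and ground truth; cohort generation derives per-image seeds from
  (base seed, group, animal, section).

Not emulated: staining variability between batches, uneven illumination,
scanner artefacts, multiple nuclei per fiber, longitudinal-section
geometry, and any colour calibration traceable to a real microscope. A
green synthetic test therefore establishes algorithmic correctness and
parameter recovery under the stated model — not robustness to every real
acquisition artefact.

## CNF scoring

The regeneration metric is the percentage of fibers with ≥ 1 central
nucleus — fiber-level counting, not nucleus-level, following the
convention of reporting "centrally nucleated fibers". Manual scoring by
eye gives no formula, so centrality is operationalised as: distance from
the nucleus point to the fiber polygon boundary > `band_frac` ·
√(area/π), with `band_frac = 0.25` by default, configurable and reported
with every result. Boundary semantics: a point exactly on the polygon edge
is *inside* for assignment (it belongs to the fiber) but *peripheral* for
centrality (distance 0). Nuclei contained in no fiber are excluded from
the tally; a nucleus inside two overlapping fiber polygons is an error,
because the annotation set, not the algorithm, is at fault.

## Group statistics

One-way ANOVA with Tukey's post-hoc test, on the animal as the unit of
replication (sections and fields are averaged, unweighted, per animal
before any test). Both entry points — raw values and printed (n, mean, SD)
summaries — use the same decomposition, which is algebraically exact for
summaries when the SD is the sample SD (n − 1 denominator); published
"± SD" values are treated as sample SDs, the field convention.

* Unequal n is handled by Tukey–Kramer:
  `se = sqrt(MSw/2 · (1/nᵢ + 1/nⱼ))`, `q = |mᵢ − mⱼ|/se`, p from the
  studentized range distribution at (k, df_within) via `ptukey` (numerical
  integration; the test suite cross-checks it against a Monte-Carlo
  simulation of the null).
* The bundled worked example — a published four-group comparison of
  gastrocnemius and diaphragm collagen in dystrophic mouse models with
  n = (3, 5, 5, 3) — reproduces the printed omnibus p-values (0.0003 and
  0.0235) from the printed summary table alone, which also identifies
  those printed values as omnibus (not post-hoc) statistics. The source
  abstract rounds the same quantities differently (0.002/0.003-level
  figures); the Results-section values are the ones reproduced here.
* Degenerate inputs: zero within-group variance with differing means
  reports p = 0 with an explicit flag; zero variance with equal means is
  an error (F undefined). Stars use strict thresholds (p = 0.05 is `ns`).
* A note on an invariant that is *false* in its naive form: "the Tukey
  adjusted p is never smaller than the unadjusted pairwise t-test p" only
  holds when the unadjusted test uses the same pooled MSw and df_within.
  Against a plain two-sample t-test the pooling itself can shrink the SE
  under variance heterogeneity. The test suite asserts the correct,
  same-pooling form.

## Pipeline conventions

Each manifest row (one image file) is one field/section record; fields are
averaged into sections and sections into animals with unweighted means at
each level. Statistics run per muscle and metric at α = 0.05 with no
additional multiplicity correction across muscles. Row-level failures
(unreadable image) are recorded in the per-image table and excluded from
aggregation; an animal with zero successful rows is dropped with a
warning. Reports are deterministic given config, manifest and seeds.

## Known limitations

* The lightness threshold, k-means configuration and cluster-naming rule
  are documented defaults, not constants recovered from any reference
  instrument; cross-study comparability requires freezing them per study.
* Percent collagen with the literal whole-image denominator conflates
  tissue coverage with fibrosis; prefer the tissue denominator when
  section size varies.
* The CNF stage consumes annotations; automated fiber/nucleus detection
  from real micrographs is out of scope.
* Synthetic validation bounds error under the generator's model only (see
  above); the ~1 point nucleus-driven blue offset is inherent to a pure
  red/blue/white partition and cancels in group contrasts.
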