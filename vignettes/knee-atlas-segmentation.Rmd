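---
title: "Atlas-seeded fuzzy segmentation of knee-joint bone structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-seeded fuzzy segmentation of knee-joint bone structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneeatlas)
```

## The problem

Extracting the patella, femur and tibia from knee-joint image series —
transverse-plane CT of the lower limb or sagittal-plane T1-weighted MR —
is the first step of several orthopaedic work-ups (patellar chondromalacia
assessment, 3D modelling of bone heads for knee-replacement planning).
Done by hand it is slow and poorly reproducible; plain intensity methods
under- or over-segment because bone, cartilage and soft tissue overlap in
intensity. `kneeatlas` implements a fully automatic alternative: a compact
statistical *atlas* of where each bone sits and how large it is at every
normalized position within a series, used to seed and to constrain two
classical fuzzy segmentation methods.

## The model

**Normalized slice position and the 11 sets.** Series differ in slice
count (17–24 sagittal MR, 25–33 transverse CT), so slice `i` of an
`n`-slice volume is binned into one of 11 position sets by the
endpoint-anchored rule

    set(i, n) = min(11, floor(11 (i - 1) / (n - 1)) + 1),

which is monotone, sends the first/last slice to sets 1/11, and is the
identity when `n = 11`. Eleven bins keep the atlas faithful without making
each bin too thin to average; the bin count is a fixed design constant of
the atlas, not a tuning knob.

**The atlas.** From an expert-annotated teaching group, every slice
contributes per-bone features: the mask centroid in normalized image
coordinates (`x = col/(w-1)`, `y = row/(h-1)`), the bone area as a fraction
of the knee area, the 8-connected boundary and the medial-axis skeleton.
Per set and bone the centroids (over slices where the bone is present) and
area fractions (over all member slices, absences counting as zero) are
averaged, pooled across subjects. A bone is *present* in a set when it is
present in at least half of the member slices — which is why the sagittal
patella carries `(0, 0)` sentinels in sets 1, 2 and 11 — and carries two
averaged centroids when most of its slices split into two major components
(the femoral condyles in the deepest transverse set; the tibial plateau
around the intercondylar eminence in the shallowest). The packaged
reference atlas (`load_reference_atlas()`) ships the published values for
both planes; `build_atlas()` constructs the same structure from any
annotated teaching group.

**Matching.** To compare slices across series the package scores
similarity on *fuzziness maps* rather than raw intensities. For each pixel,
the intensities of its `w × w` window (default `w = 3`, edge-replicated)
are rescaled to memberships `mu = (I - min)/(max - min)` and summarized by
the De Luca–Termini logarithmic entropy or the quadratic energy index,
both normalized to `[0, 1]` and maximal at `mu = 0.5`. The map highlights
intensity transitions (bone boundaries) and is invariant to affine
intensity changes. Note one degenerate property: a *perfectly* two-valued
window has crisp memberships and therefore zero fuzziness; real edges are
sampled with intermediate levels and light up as intended. Similarity
itself is one of three intensity-based measures: normalized
cross-correlation (NCC, Pearson over pixels), gradient correlation (GC,
the mean NCC of 3×3 Sobel derivative pairs; averaging keeps the score in
`[-1, 1]`), and gradient difference (GD, Lorentzian-weighted residuals of
the derivative images with a scale factor `s`, 1 for same-size images;
matching runs at 256×256). Histogram measures (mutual information) and raw
difference measures (SSD/SAD) are deliberately not offered. Best matches
maximize the score; ties break to the lowest candidate index for
determinism.

**Seeded segmentation with an area guard.** The atlas centroid(s) of the
slice's set become seed points; the atlas area fraction times the knee
area becomes a target area. Two engines share this interface:

* *Fuzzy connectedness (FC).* Adjacent pixels (8-adjacency) get an
  affinity `w1 G((I_c+I_d)/2; mu_o, sd_o) + w2 G(|I_c-I_d|; 0, sd_g)` with
  unit-peak Gaussians `G`, `w1 = w2 = 0.5`, and object statistics
  estimated in a radius-3 disc around the seed (`sd_g` from the
  adjacent-pixel steps in that disc, floored at 1e-3 of the intensity
  range so flat discs cannot degenerate). A pixel's connectivity is the
  maximum over paths from the seed of the minimum affinity along the path
  — computed by best-first propagation, and verified in the tests against
  Floyd–Warshall and exhaustive path enumeration oracles.
* *Fuzzy c-means (FCM).* Standard alternating updates of memberships
  (`u = 1/sum((d_i/d_j)^(2/(m-1)))`) and centers on the pixel
  intensities, with `c = 3` classes (background, soft tissue, bone),
  fuzzifier `m = 2`, tolerance 1e-4 on the membership change, at most 200
  iterations, and a deterministic initialization from the seed intensities
  plus intensity quantiles. The cluster dominating at the seed provides
  the membership map.

Either way a scalar map in `[0, 1]` results, and the *area guard*
thresholds it: among the nested seed components of `{map >= tau}`, the
threshold whose component area is closest to the atlas target wins (ties
to the larger threshold, i.e. the smaller mask; found by bisection over
the sorted unique map values, which the tests compare against an
exhaustive sweep). The guard is the package's protection against
over-segmentation; a result that cannot come within 15% (configurable) of
the target is flagged rather than rejected.

**Patella seed relocation (sagittal only).** The averaged patella centroid
often falls just outside the thin, crescent-shaped patella, in which case
the seed statistics describe soft tissue and the extraction is wrong
despite a conforming area. The fix follows the atlas's own logic: pixels
are assigned to their dominant FCM cluster; the cluster dominant outside
the knee mask is background, the one dominant inside is soft tissue, and
whatever remains inside the knee is bone-like. Candidate seeds on the
skeleton of that bone-like region are visited in increasing distance from
the atlas centroid (ties in row-major order) and the first whose guarded
extraction area conforms is adopted. Identifying the candidate region by
*role* rather than by the cluster under the (possibly off-structure) seed
is what makes the step work on both contrast polarities.

**Post-processing.** A 3×3 mean filter (majority vote), morphological
opening then closing with a radius-1 disc, hole filling, and retention of
the seed component(s) yield a single smooth-edged structure per seed.

**Evaluation.** Dice index as a percentage (`100·2|A∩B|/(|A|+|B|)`; two
empty masks give a flagged 100 and are excluded from aggregation), column
means with half-up rounding to two decimals (the printed precision of the
reference tables), Bland–Altman statistics on `d = FCM − FC` (FC is the
reference method; negative means mean FC is better), the two-sided
Wilcoxon signed-rank test (exact up to n = 25 after dropping zero
differences) and the one-sided paired t-test with alternative "FCM < FC".
Per-series Dice against ground truth is volumetric: intersections and
areas are summed over slices before forming the ratio, so 4-pixel patella
slices at the series edges do not dominate the per-case number.

## The phantom generator

Clinical CT/MR series cannot be shipped, so `phantom_spec()` /
`generate_volume()` synthesize series that exercise every pipeline branch:
17–24-slice sagittal "MR" or 25–33-slice transverse "CT" volumes (defaults
20 and 28) at 256×256, with a knee-shaped region (a large ellipse, unioned
with a 3-pixel dilation of the bones so the knee is always a superset) and
three disjoint bone-like structures — a lens-shaped patella (intersection
of two discs), an elliptical femur that splits into two condyle discs in
transverse set 11, and an elliptical tibial plateau that splits into two
lobes in transverse set 1, exercising both dual-centroid paths. Per-set
areas follow the packaged reference area profile (so the sagittal patella
is absent in sets 1, 2 and 11 and shrinks to a few pixels in set 10);
shapes are sized analytically from the target area, so at zero noise and
zero jitter the masks equal the analytic geometry exactly. CT-like
phantoms are bright-bone (background 20 < tissue 80 < bone 200), MR-like
ones invert the bone/tissue contrast (bone 90 < tissue 190), forcing the
segmentation to be polarity-agnostic. Gaussian noise defaults to 5% of the
bone–tissue contrast; per-subject geometry jitter (sd 0.02 normalized
units) displaces each bone, and a volume whose jittered bones overlap is
regenerated with halved jitter (at most 10 attempts). Bone *positions* are
the package's own layout, chosen for guaranteed disjointness, not the
published centroid tables — the phantoms validate the machinery, not the
published anatomy.

What the phantoms deliberately do not model: anatomical shape detail,
intensity inhomogeneity (bias fields), partial-volume edges, cartilage,
or inter-slice anatomical drift. Passing the phantom closure therefore
shows that the atlas/seeding/guard machinery is correct and stable under
noise and geometric variation — not that clinical Dice levels would be
reproduced; the published per-case Dice tables are shipped as data for
the evaluation stage instead.

## A worked run

```{r closure, eval = FALSE}
# atlas from a synthetic teaching group
teaching <- generate_teaching_group(10, phantom_spec("sagittal", rng_seed = 1000))
atlas <- build_atlas(teaching)

# held-out subject, default 5%-contrast noise
ph <- generate_volume(phantom_spec("sagittal", rng_seed = 2001))
run <- run_pipeline(run_config("sagittal", "MR", "FC", atlas = atlas),
                    ph$volume, truth_masks = ph$masks)
run$dice
```

At these settings (the ones `scripts/acceptance.R` re-runs: 10 teaching
subjects, 5 held-out subjects, 256×256, default noise and jitter) the
per-bone mean volumetric Dice is above 99% for both engines and the FC−FCM
gap is a fraction of a percentage point, consistent in sign and order of
magnitude with the ~1-point FC advantage reported on clinical data.

## Numerical and design choices

* **Working size 256×256** for matching and segmentation; masks return to
  the input size by nearest neighbour. This makes the GD scale factor 1
  valid and atlas area fractions comparable across series.
* **Coordinates.** Normalized centroids use 0-based pixel positions over
  `(size - 1)`, so table values round-trip to pixels exactly; R-facing
  seed points are 1-based.
* **Degenerate inputs.** Constant slices normalize to all zeros rather
  than NaN; constant windows have zero fuzziness; NCC errors only when
  both rasters are constant (one constant raster scores 0); FC affinity
  sds are floored; FCM refuses fewer distinct intensities than clusters.
* **Determinism.** No randomness anywhere in the segmentation path; FCM
  initialization is quantile-based; phantom volumes are bit-reproducible
  from their seed; ties (matching, thresholds, relocation) break by fixed
  rules.
* **Set averaging** pools slices across subjects rather than averaging
  per-volume first; skeletons and boundaries are kept per teaching slice
  and never averaged (only centroids and areas feed segmentation).
* **Knee area without a mask** is estimated as the largest Otsu foreground
  component with holes filled; with expert masks supplied, those are used.
* **Test problem sizes.** Unit tests run on 64-pixel phantoms; the
  closure check uses the full 256-pixel, 10+5-subject configuration. The
  connectivity oracle is exhaustive over all 2-level rasters up to 3×3 and
  all 3-level 2×2 rasters and sampled (fixed seed) over 3-level 3×3 and
  4×4 rasters, since exhaustive 3-level 4×4 enumeration (3^16 ≈ 43M
  rasters) is not tractable; the dynamic-programming oracle is itself
  validated by exhaustive path enumeration on the small sizes.

## Known limitations

* DICOM series are not read directly; convert to NIfTI first.
* The matching stage selects whole slices; there is no spatial transform,
  sub-pixel alignment or deformable registration.
* The atlas is 2D and per-plane: transverse CT and sagittal MR only,
  matching the packaged tables; other plane/modality combinations need
  their own teaching group via `build_atlas()`.
* The FC threshold is chosen by the area guard alone; no fixed
  connectivity cut is exposed.
* PNG output is 8-bit; use NIfTI for lossless intensity round-trips.
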