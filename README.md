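# kneeatlas

Fully automatic extraction of the three bone structures of the knee joint
— patella, femur and tibia — from series of 2D grayscale slices
(transverse-plane CT of the lower limb, or sagittal-plane T1-weighted MR
of the knee), for image-analysis work in orthopaedics: chondromalacia
assessment, 3D bone modelling, and knee-replacement planning, where manual
delineation is the slow and irreproducible bottleneck.

## Method

The pipeline is atlas-seeded fuzzy segmentation:

1. **Inter-series matching.** Slices are compared on per-pixel *fuzziness
   maps* — window memberships `μ = (I − min)/(max − min)` summarized by the
   De Luca–Termini entropy `H = −(1/(n ln 2)) Σ [μ ln μ + (1−μ) ln(1−μ)]`
   (or the quadratic energy `E = (1/n) Σ 4μ(1−μ)`) — scored with
   intensity-based similarity measures: NCC (Pearson over pixels), GC
   (mean NCC of 3×3 Sobel derivative images) or GD (Lorentzian-weighted
   gradient residuals, scale `s = 1` at the common 256×256 working size).
2. **The 11-set atlas.** Each slice of an `n`-slice volume is assigned to
   set `min(11, ⌊11(i−1)/(n−1)⌋ + 1)`. From an annotated teaching group
   the atlas stores, per set and bone, the mean normalized centroid(s) and
   the mean bone area as a fraction of the knee area. Two sets carry dual
   centroids (femoral condyles in transverse set 11, tibial plateau lobes
   in transverse set 1); the sagittal patella is absent in sets 1, 2
   and 11. The published reference atlas for both planes is packaged.
3. **Seeded fuzzy segmentation.** Atlas centroids seed either fuzzy
   connectedness (max–min path strength over Gaussian pair affinities,
   best-first propagation) or fuzzy c-means (`c = 3`, `m = 2`,
   deterministic initialization); an **area guard** then thresholds the
   connectivity/membership map at the level whose seed component is
   closest in area to the atlas prior — the protection against
   over-segmentation. On the sagittal plane the patella seed is first
   relocated onto the skeleton of the bone-like FCM cluster, nearest
   candidate first, until the extraction area conforms.
4. **Post-processing and evaluation.** Mean filtering, opening/closing,
   hole filling, seed-component selection; Dice (%), per-column means,
   Bland–Altman limits of agreement and paired Wilcoxon/t-tests, with the
   published per-case Dice tables packaged as reference data.

A synthetic phantom generator (`phantom_spec()`, `generate_volume()`)
produces CT-like and MR-like series with ground-truth masks that follow
the atlas area profile, so the whole pipeline is testable offline.

## Worked example

Build an atlas from a synthetic teaching group and segment a held-out
phantom subject with fuzzy connectedness:

```r
library(kneeatlas)

teaching <- generate_teaching_group(4, phantom_spec("sagittal", rng_seed = 1000))
atlas    <- build_atlas(teaching)

ph  <- generate_volume(phantom_spec("sagittal", rng_seed = 2001))
run <- run_pipeline(run_config("sagittal", "MR", "FC", atlas = atlas),
                    ph$volume, truth_masks = ph$masks)
run
#> <knee_run> FC on 'phantom-sagittal-2001' (20 slices)
#>   volumetric Dice vs truth:
#>     patella  99.65%
#>     femur    99.99%
#>     tibia    99.99%
```

The per-bone numbers are volumetric Dice percentages against the phantom's
ground truth; near-100 values mean the atlas seeds landed in (or were
relocated into) each bone and the area guard stopped growth at the right
boundary. The packaged reference data reproduce the published summaries:

```r
load_reference_atlas("sagittal", "MR")$sets[[3]]$bones$patella$centroids
#>          x     y
#> [1,] 0.188 0.324

aggregate_dice(load_reference_dice("ct"), "patella", "FC")
#> [1] 89.48

dice_report(load_reference_dice("fastmri"))
#> patella  mean Dice: FC 86.18, FCM 85.33; diff -0.851 +/- 0.720; Wilcoxon p 0.01367, t-test p 0.00233
#> femur    mean Dice: FC 88.19, FCM 87.55; diff -0.640 +/- 0.256; Wilcoxon p 0.001953, t-test p 1.22e-05
#> tibia    mean Dice: FC 87.12, FCM 86.57; diff -0.552 +/- 0.374; Wilcoxon p 0.008004, t-test p 0.0005823
```

Negative Bland–Altman means (`FCM − FC`) show fuzzy connectedness
consistently ahead of fuzzy c-means by well under one Dice point.

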