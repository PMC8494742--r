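---
title: "Quantifying capillary congestion on en-face OCTA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying capillary congestion on en-face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octacongest)
```

## The problem

In chronic branch retinal vein occlusion (BRVO) the macula can remain dry
for months and then relapse into macular edema (ME). En-face OCT
angiography resolves the retinal capillaries into a superficial (SCP) and a
deep (DCP) plexus, and in chronic BRVO the deep plexus often shows
*capillary congestion*: expanded, bright, coarse capillary networks
bridging the affected (nonperfused) and normal vasculature. This package
quantifies that phenotype and its relation to edema recurrence: it derives
the named region system from binary masks, detects congestion from pixel
rules, measures region morphometry, registers follow-up thickness maps to
baseline, maps the per-pixel ratio of increased retinal thickness (RIRT),
and fits the cohort-level recurrence model. Because no patient images are
distributed with studies of this kind, a phantom generator with complete
ground truth stands in for the acquisition device, and every stage is
validated against closed-form or brute-force oracles on those phantoms.

## Image model and geometry

All rasters live on a square, fovea-centred grid. The reference acquisition
is a 6.0 mm field sampled at 600 px per side, i.e. a pitch of 10 um/px
(`pixel_pitch_um(6, 600)`), with angiograms stored as 16-bit gray scale.
Coordinates are 1-based, row = y (downward), column = x (rightward), and a
pixel's centre sits at integer (x, y). Connectivity is 8-neighbour
throughout (components, skeletons, plateau grouping).

## The congestion pixel rules

The detector makes the descriptive criteria operational on the
gamma-corrected image (`gamma_correct`, exponent 3.0, which brightens the
mid-range and makes the congestion boundary visible):

* **bright** — component gray level at or above 50% of full scale
  (>= 32768 on 16 bits). The component statistic is the **median** by
  default; the mean is available via `brightness_stat = "mean"`. Whether
  the original manual readings judged brightness on the raw or the
  corrected image is not documented for this instrument class; the default
  is the corrected image (the gamma step is introduced precisely to
  delineate congestion) and `brightness_on = "raw"` switches it.
* **expanded** — any skeleton caliber strictly above 2.0 px. Calibers are
  `2 d - 1` at skeleton pixels, where `d` is the Euclidean distance to the
  nearest background pixel: an n-px ribbon then reads ~n px at its
  centreline (the naive `2 d` overshoots by one pixel because `d` runs
  from the centre pixel to the first *background* pixel).
* **coarse** — the within-component caliber range strictly above 2.0 px.

How the three descriptors combine is not specified by the phenotype's
prose; the default is `bright AND (expanded OR coarse)`, because a strict
conjunction would reject uniformly dilated bright collaterals that clearly
belong to the phenotype, while a disjunction would admit dim normal
vessels. `rule_mode = "all"` and `"any"` are provided. Qualifying
components must meet the band within `boundary_band_px` (default 20 px) of
the abnormal/normal interface — congestion is by definition *between* the
affected and normal vasculature — and the FAZ is always excluded. The
output is the filled footprint of the qualifying components, mirroring the
region-style masks a human grader draws.

Vessel extraction thresholds the corrected image at `vessel_threshold`
(default 13107, 20% of full scale) and removes components below
`speckle_min_px` (default 5 px). These two parameters are
instrument-dependent; on the phantoms the defaults recover the generating
network with IoU >= 0.9.

## Region algebra and morphometry

Per layer, `{abnormal, normal, FAZ}` partitions the frame: the normal
region is the complement of the abnormal region except the FAZ. When an
abnormal mask overlaps the FAZ, FAZ wins (congestion and abnormal
selections exclude the FAZ by definition) and the repair is flagged. The
transitional zone is the Hadamard product of SCP-normal and DCP-abnormal.
The deep congestion is partitioned into its part inside the TZ and its
part under SCP-A, plus an explicit *residual* class: the scheme implies
the residual is empty (DCP-C lies within DCP-A), and making it a reported
quantity turns that assumption into a checkable invariant.

Morphometry is deliberately elementary: area is `pixel count x pitch^2`,
and region VD / MRT are arithmetic means of the decoded maps over the
mask, with invalid-decode pixels excluded and counted. Total-frame VD/MRT
rows include the FAZ (the exclusion convention for frame totals is not
documented for the instrument; including it is the simpler convention and
is stated here). A recomputed VD (box-filtered binary vessel fraction,
`vd_from_vessels`) is available for phantoms, but region VD defaults to
the decoded device-style map, which is what clinical tables report.

## Color-map codec

Device exports encode thickness (um) and VD (%) as 24-bit color maps. The
actual conversion tables are proprietary, so the codec is defined by an
explicit LUT: ordered (scalar, RGB) control points, piecewise-linear in
RGB. Encoding interpolates and rounds to 8 bits; decoding projects each
color onto a densely sampled path (4096 samples, ties toward the lower
scalar) and flags colors farther than `tol = 10` RGB units as invalid
(more than 5% invalid pixels is an error naming the worst offenders).
Correctness is the round-trip contract: `|decode(encode(x)) - x|` is
bounded by one *quantization step* — the scalar change per RGB quantum on
the slowest segment, `lut_quantization()`, about 0.49 um for the default
five-knot rainbow over 0-500 um. The pipeline's science is LUT-agnostic;
user LUTs load from CSV.

## Registration and the RIRT map

Between-visit eye motion is modelled as a 2-D affine fitted by least
squares to manually picked bifurcation control points (>= 3, non-collinear
sources; exact interpolation at 3). Follow-up maps are warped onto the
baseline grid by inverse mapping with bilinear interpolation
(nearest-neighbour for label maps); pixels sampling outside the source are
marked invalid and excluded from all downstream statistics via the
overlap mask. No outlier rejection is performed on control points — a
residual ceiling (default 5 px) warns instead, because silently dropping
points would hide digitisation errors.

RIRT is the elementwise follow-up/baseline thickness ratio on the overlap.
Two thresholds coexist deliberately and differ in strictness:

* the **ME territory** is the *strict* superlevel set RIRT > 1.1 ("more
  than a 10% increase"), contoured by marching squares;
* the **eye-level recurrence rule** is *inclusive*: CSMT at follow-up
  >= 1.10 x baseline ("increased by 10% or more").

Apexes are local maxima of a Gaussian-smoothed copy of the map (sigma
2 px by default, recorded in the output; smoothing suppresses single-pixel
maxima), restricted to the territory, ranked by value with raster-order
tie-breaking, and labelled FAZ / NPA / other by mask membership. The
clinical judgment "due to any fluids" in the recurrence definition is not
modelled; the classifier is purely numeric.

## The phantom generator

The generator emulates the study inputs, not retinal physiology:

* **Vessel networks** are seeded random branching walks rasterized at
  caliber 1-2 px — sufficient to exercise caliber/brightness rules, which
  are purely geometric and photometric. No flow model is implied.
* **Nonperfusion** is an angular sector beginning outside the FAZ; the
  deep sector is strictly wider than the superficial one, so DCP-A
  strictly contains SCP-A and the TZ is the angular ring between them.
* **Congestion** is a wavy dilated strand (caliber oscillating over
  3-6 px, brightness 0.7 of full scale) along each deep sector edge, a few
  pixels inside the border, with short spurs touching the interface. A
  2-px avascular rim separates the normal network from the abnormal
  border, keeping congested and normal vessels distinct components of the
  flow image — real congested collaterals do anastomose with the normal
  bed, so detection on clinical images will be harder than on phantoms.
* **Thickness** is a constant background (250 um) with a Gaussian foveal
  dip (12%, sigma 400 um); edema multiplies it by an isotropic
  raised-cosine blob (default peak ratio 1.5, radius 1.5 mm at the fovea),
  chosen for a closed-form territory that oracle tests can enumerate. The
  follow-up map is evaluated analytically as the baseline-times-edema
  field composed with the inverse of the configured affine motion, so
  registration tests know the exact truth.
* **Randomness** all flows through one seed (`withr::with_seed`); cases
  are bit-reproducible.

What phantoms do *not* emulate: speckle statistics of real OCTA,
projection artifacts, segmentation (slab) errors, aneurysmal dilatation
(no quantitative phenotype is documented for it, so it is omitted rather
than guessed), anastomoses between congested and normal vessels, and
clinically sized congestion areas (the phantom corridor is ~0.2 mm^2,
an order below typical clinical extents — enough to exercise every rule,
but passing detector tests on phantoms does not certify performance on
patient images).

## The simulated cohort

`simulate_cohort` draws the deep-congestion MRT from N(264.8, 30.2) um and
total injections from a negative binomial with mean 3.4 and SD 3.2 —
study-cohort moments — and generates recurrence from
`logit p = b0 + log(1.044) MRT + log(1.803) INJ`, the per-unit odds
ratios of the reference multivariate model. The intercept is calibrated
by deterministic quadrature so that the model-implied *marginal*
recurrence rate equals 22/76 (28.9%): anchoring the linear predictor at
the covariate means would overshoot the marginal rate, because the
logistic is convex below one half. Ancillary covariates (age, acuity,
baseline CSMT, follow-up period) are drawn at study moments for table
shape only and do not enter the generating model — so univariate screens
on them are null checks, not recoveries.

The statistical layer mirrors standard clinical reporting: two-sided
p-values, Mann-Whitney U (exact enumeration when both n <= 10 without
ties, otherwise a tie- and continuity-corrected normal approximation),
Wilcoxon signed-rank, Pearson chi-squared (warning below expected count 5,
echoing the usual Fisher fallback), Fisher's exact, Spearman correlation
by mid-ranks with a t-approximation, and logistic regression with Wald
CIs (profile CIs would be tighter near separation, but Wald is what
clinical software prints). Multivariate terms are those univariately
significant at 0.05 — an explicit, overridable rule; no multiplicity
correction is applied by default (`holm_adjust` exists for users who want
it). Separation and non-convergence are flagged on the affected rows.

## Numerical choices and degenerate inputs

* Caliber at even ribbon widths rounds down by ~1 px (the skeleton sits
  off-centre); the expanded criterion is unaffected because it is a strict
  `> 2.0` on dilated (>= 3 px) vessels.
* The recurrence boundary uses a small epsilon guard so that exact 10%
  increases (e.g. 300 -> 330 um) classify as recurrent despite binary
  floating point.
* `or_derivations` computes the doubling increment as the smallest integer
  k with OR^k >= 2, with an epsilon guard at exact powers; OR <= 1 is an
  error (no doubling exists).
* Empty masks yield flagged NA metrics, never silent zeros; empty
  territories yield empty apex lists; zero-baseline RIRT pixels are
  excluded and counted, with an error above 10%.
* Degenerate phantom geometry (FAZ beyond the half-frame, abnormal sector
  overlapping the FAZ or not fitting the frame) is rejected at
  configuration time.

## Problem sizes used in the shipped analyses and tests

The analysis scripts run the full 600 x 600 geometry. The test suite runs
most oracle checks on 200 x 200 phantoms at 30 um/px — same physical
field, coarser grid — and the detector acceptance on ten full-size
phantoms; the parameter-recovery checks use n = 5000 simulated eyes and
100 null replicates at n = 2000. These sizes were chosen so the whole
suite completes in a couple of minutes while keeping every check at the
full acquisition geometry where it matters (detector, RIRT).

## Known limitations

Manual-grading adjudication (two readers plus a referee) is outside
computational scope: the package takes drawn masks as inputs and offers
the rule-based detector as a reproducible alternative, but it does not
model inter-reader variability. The device's internal OCTA reconstruction
and its true color tables are proprietary and are replaced by documented
stand-ins. Phantom-calibrated defaults (vessel threshold, speckle floor,
boundary band) will need instrument-specific adjustment on clinical
exports.
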