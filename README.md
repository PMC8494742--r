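# octacongest

Quantitative analysis of **capillary congestion** on en-face OCT
angiography (OCTA) in chronic branch retinal vein occlusion (BRVO), for
retinal imaging researchers who need the whole measurement chain — from
device-style raster exports to the cohort-level recurrence model — as
reproducible, tested code.

In chronic BRVO the deep capillary plexus (DCP) frequently develops
congestion: expanded, bright, coarse capillary networks bridging the
nonperfused and normal vasculature. The package implements:

* **Pixel-rule congestion detection** on gamma-corrected (γ = 3.0) 16-bit
  angiograms: *bright* (gray level ≥ 50 % of full scale, i.e. ≥ 32768),
  *expanded* (skeleton caliber > 2 px from the Euclidean distance
  transform), *coarse* (within-vessel caliber fluctuation > 2 px),
  combined as `bright ∧ (expanded ∨ coarse)` on 8-connected vessel
  components near the abnormal/normal boundary, FAZ excluded.
* **Region-mask algebra**: per-layer partition {A, N, FAZ} with
  N = ¬(A ∨ FAZ); transitional zone TZ = SCP-N ⊙ DCP-A (Hadamard
  product); the DCP-C partition into TZ / under-SCP-A / residual parts
  with exact pixel-count conservation.
* **Morphometry**: region area (mm², % of the 6 × 6 mm frame at
  10 µm/px), mean vessel density and mean retinal thickness (MRT) over
  any mask, via a color-map codec (piecewise-linear LUT, nearest-path
  decoding with validity masking) replacing the proprietary conversion.
* **Registration & RIRT**: least-squares 2-D affine from bifurcation
  control points; inverse-mapped bilinear warping with an overlap mask;
  the per-pixel ratio of increased retinal thickness
  RIRT = T_followup / T_baseline; the macular-edema territory as the
  strict superlevel set RIRT > 1.1 with marching-squares contours; apex
  localisation and FAZ/NPA labelling; the inclusive eye-level recurrence
  rule CSMT_followup ≥ 1.10 × CSMT_baseline.
* **Cohort statistics**: Mann–Whitney U, Wilcoxon signed-rank,
  χ²/Fisher, Spearman correlation, univariate → multivariate binary
  logistic regression with Wald CIs (odds ratio per µm of DCP-C MRT and
  per injection), and odds-ratio derivations
  ((OR − 1) × 100 % per unit; smallest k with OR^k ≥ 2).
* **Phantoms**: a synthetic-case generator (vessel networks, sector
  nonperfusion, congestion corridor, FAZ, thickness/VD maps, focal edema
  under a known affine motion) with complete ground truth, plus a
  simulated cohort with a known logistic recurrence model — so every
  stage is testable without patient data.

## Worked example

The `analysis/` scripts run the pipeline end to end on the default
phantom (600 × 600 px, 10 µm/px, seed 1):

```sh
Rscript analysis/01_generate_phantom.R
Rscript analysis/02_segment_measure.R
Rscript analysis/03_register_rirt.R
Rscript analysis/04_cohort_analysis.R
```

Stage 2 detects the congestion corridor and tabulates the regions:

```
Detector IoU vs ground-truth DCP-C: 1.000
DCP-C partition: 100.0% in TZ, 0.0% under SCP-A, residual 0 px
  region area_mm2 area_pct mean_vd_pct mrt_um
1  SCP-A   8.7625  24.3403      0.3948  249.6
2  DCP-A  11.9327  33.1464      1.6764  249.6
3  DCP-N  23.4297  65.0825     34.2658  249.4
4  DCP-C   0.2029   0.5636     25.7110  249.1
5     TZ   3.1702   8.8061      6.1534  249.5
```

The detector recovers the generating corridor exactly (IoU 1.0); the
nonperfused regions have near-zero vessel density while the normal deep
plexus sits at ~34 %, and this phantom's corridor lies entirely in the
transitional zone. Stage 3 registers the follow-up visit and maps the
edema:

```
Affine fit: rms residual 2.10e-14 px; max |M - truth| = 2.49e-14
RIRT: territory mean 1.267 / max 1.499 over 35184 px; DCP-C mean 1.046 / max 1.322
Apexes: 1; top apex at (301, 300) in FAZ, RIRT 1.499
CSMT 229.2 -> 328.8 um: recurrence TRUE
```

The fitted affine matches the simulated eye motion to machine precision,
the territory's RIRT dominates that of the congestion region, the apex
falls in the FAZ, and the central-subfield rise (229 → 329 µm, +43 %)
triggers the recurrence rule. Stage 4 simulates the 76-eye cohort and
refits the recurrence model; at n = 5000 the generating odds ratios are
recovered:

```
Recovery at n = 5000: OR(MRT) = 1.0409 (true 1.044), OR(inject) = 1.762 (true 1.803)
```

## Method documentation

`vignettes/octacongest-methods.Rmd` documents the models, the parameter
defaults and their units, what the phantoms do and do not emulate, the
numerical edge cases, and the design decisions taken where the underlying
workflow was manual or instrument-specific.
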