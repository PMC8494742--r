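Package: octacongest
Title: Quantitative En-Face OCT Angiography Analysis of Capillary
    Congestion in Branch Retinal Vein Occlusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying capillary congestion on en-face optical
    coherence tomographic angiography (OCTA) in chronic branch retinal vein
    occlusion. Implements color-map decoding of device thickness and
    vessel-density maps, pixel-rule detection of congested capillaries
    (expanded, bright, coarse) after gamma correction, named region-mask
    algebra (abnormal/normal/FAZ partitions, transitional zone, congestion
    partition), region morphometry (area, mean vessel density, mean retinal
    thickness), control-point affine registration of follow-up scans, the
    ratio-of-increased-retinal-thickness (RIRT) map with macular-edema
    territory contouring and apex localisation, and the cohort-level
    statistical layer (group comparisons, Spearman correlation, logistic
    recurrence modelling with odds-ratio derivations). Ships a synthetic
    phantom generator with full ground truth so the whole pipeline is
    exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
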