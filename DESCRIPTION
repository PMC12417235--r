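Package: odacs
Title: Occlusion-Downstream Area Collateral Scoring for Acute Ischemic Stroke Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes quantitative and categorized cerebral collateral scores
    from CT angiography vessel segmentations and CT perfusion Tmax maps. The
    occlusion-downstream area is defined by thresholding the Tmax map
    (hypoperfusion at Tmax > 6 s), refined by 3D morphological closing with an
    ellipsoidal structuring element so that vessels carved out of vendor
    perfusion maps are recovered, and mirrored across the brain midline plane
    to obtain a contralateral reference region. The collateral score is the
    ipsilateral to contralateral vessel-volume ratio, categorized on the Tan
    ordinal scale (with relaxed 5%/95% boundary criteria) and an extended
    six-level variant. Also provides an atlas-based middle cerebral artery
    territory reference score, cohort comparison statistics (Bland-Altman
    limits of agreement, one-sided Wilcoxon signed-rank tests, quadratically
    weighted Cohen's kappa, confusion matrices, good-to-poor shift
    proportions), and a synthetic phantom generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
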