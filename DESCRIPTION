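Package: pvsfrac
Title: Perivascular Space Volume Fraction from T2-Weighted Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated quantification of the total white-matter
    perivascular space volume fraction (PVSvf) from 3D T2-weighted brain
    MRI. Builds the normal-appearing white-matter region of interest by
    mask arithmetic with millimetre-exact anisotropic CSF dilation,
    normalizes signal intensity from the image histogram, applies a
    multi-scale 3D Frangi vesselness filter tuned for bright tubular
    perivascular spaces on anisotropic voxel grids, thresholds the
    vesselness map and reports PVS volume and volume fraction. Includes a
    ground-truthed synthetic phantom generator (tubular PVS, CSF rim,
    hemorrhage- and hyperintensity-like lesions, Rician noise) and the
    accompanying statistical battery: Welch's ANOVA with omega-squared,
    Games-Howell pairwise comparisons with Cohen's d, Spearman rank
    correlation, intraclass correlation, Bland-Altman limits of
    agreement, linear regression summaries, Monte-Carlo power for Welch's
    ANOVA, and median/IQR recovery from category counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
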