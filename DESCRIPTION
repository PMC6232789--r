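Package: femri
Title: Parametric Iron MRI Mapping and Macrophage Deposit Cluster Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying nanoparticle and endogenous iron contrast
    in tumors from multi-gradient-echo (MGE) magnetic resonance images.
    Provides pixel-wise monoexponential T2*/R2* relaxometry, linear
    R2*-to-iron calibration producing parametric iron concentration (FeMRI)
    maps, concentration-stratified connected-component cluster
    quantification of localized high-iron deposits, matched histological
    deposit mapping (iron-positive pixel detection, downsampling to MRI
    resolution, watershed discretization, per-deposit cell counting),
    macrophage polarization frequency statistics, and a simulation harness
    contrasting localized cluster counting with conventional whole-ROI
    distribution statistics. A synthetic phantom module generates MGE
    series and histology sections with known ground truth for testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    EBImage,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
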