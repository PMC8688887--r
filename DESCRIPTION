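Package: tvdmri
Title: Tensor-Valued Diffusion MRI: Simulation, Kurtosis Separation and
    Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing diffusion MRI acquired with multiple
    b-tensor shapes (linear and spherical tensor encoding). Provides a
    synthetic phantom cohort generator with Rician noise, a powder-averaged
    cumulant fit that separates anisotropic and isotropic diffusional
    kurtosis (MK_A, MK_I) alongside conventional DTI and DKI parameters,
    morphological rim regions of interest, histogram feature extraction,
    and a nonparametric group-comparison layer (Cohen's d, rank-sum tests,
    ROC curves with bootstrap confidence intervals and Youden cut-points).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
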