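Package: octaquant
Title: Quantification of Choroidal Neovascularization Biomarkers from
    En-Face OCTA Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Batch image-processing pipeline that quantifies nine vascular
    biomarkers of myopic choroidal neovascularization (mCNV) lesions from
    manually delineated en-face optical coherence tomography angiography
    (OCTA) images. A two-branch pipeline denoises the lesion (Gaussian
    blur), enhances vessels (Hessian-based Frangi vesselness), binarizes
    them (local median thresholding) to measure area biomarkers, and in a
    second branch applies a Mexican-hat (Ricker wavelet) filter followed
    by binary thinning and skeleton-graph morphometry to measure length,
    junction, tortuosity and box-counting fractal-dimension biomarkers.
    A synthetic vascular-phantom generator with analytic ground truth
    makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    png,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
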