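Package: convergemap
Title: Convergent Causal Mapping of Frontal Visuospatial Attention Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for convergent causal mapping of visuospatial attention
    networks from neurosurgical cohorts: multivariate support-vector-regression
    lesion-symptom mapping (SVR-LSM) with direct total lesion volume control,
    permutation-based voxelwise inference and continuum family-wise error
    (CFWER) cluster correction; consensus-hub connectomics on fibre bundle
    capacity (FBC) matrices built from weighted streamline sets; simulated
    surgical disconnection correlated with postoperative deficit severity;
    kernel density mapping of intraoperative stimulation sites; and
    track-density imaging. Includes scoring of the Bells cancellation test and
    its intraoperative analogue, the group statistics and effect sizes used to
    report such studies, and a synthetic-data generator that emulates the
    statistical structure of each stage so the full pipeline can be exercised
    and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
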