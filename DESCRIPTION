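Package: csfdyn
Title: Intrathecal CSF Geometry and Hydrodynamics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies cerebrospinal fluid (CSF) geometry and pulsatile
    hydrodynamics in the spinal subarachnoid space from axial geometric
    profiles and cardiac-gated flow waveforms, with support for intrathecal
    catheter implantation studies. Provides catheter cross-section
    adjustment of subarachnoid-space profiles, hydraulic-diameter and
    volume/surface summaries, spatio-temporal smoothing-spline
    interpolation of flow waveforms, pulse wave velocity estimation,
    dimensionless-number characterization (Reynolds, Womersley,
    Keulegan-Carpenter), a Hagen-Poiseuille flow-reduction estimator for
    catheter implantation, a linear mixed-effects comparison battery with
    Bonferroni correction, and a synthetic-cohort generator so the entire
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    lme4,
    Matrix,
    jsonlite,
    yaml,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    readxl
Config/testthat/edition: 3
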