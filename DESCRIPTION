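Package: qusdr
Title: Quantitative Ultrasound Delta-Radiomics for Treatment Response Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for quantitative ultrasound (QUS)
    delta-radiomics. Generates beamformed radiofrequency (RF) frames from point
    scatterer fields with controllable attenuation, scatterer size, acoustic
    concentration and spacing regularity; estimates the seven classical QUS
    spectral parameters (mid-band fit, spectral slope and intercept, attenuation
    coefficient, scatterer spacing, average scatterer diameter and acoustic
    concentration) on sliding-window parametric maps normalized against a
    reference phantom; derives grey-level co-occurrence texture features from the
    maps; assembles per-patient delta features relative to a pre-treatment
    baseline; and evaluates k-nearest-neighbour and naive-Bayes response
    classifiers with sequential forward selection under leave-one-out
    cross-validation, together with group-comparison and Kaplan-Meier survival
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC
Config/testthat/edition: 3
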