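Package: lactowave
Title: Microwave Dielectric Spectroscopy of Bovine Milk for Pregnancy
    Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and bounded complex nonlinear least-squares
    fitting of the Cole-Cole + dc-conductivity + Jonscher permittivity model
    for raw-milk microwave spectra (0.5-40 GHz), a synthetic longitudinal
    cohort generator emulating weekly, daily and random sampling designs with
    pregnancy-stage-dependent parameter dispersion and a negative fat-
    dielectric-strength coupling, staged variability-reduction statistics,
    Pearson correlation and PCA summaries of the fitted parameters, and a
    self-normalizing neural-network (SELU) pregnancy classifier with
    reproducible seeding end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
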