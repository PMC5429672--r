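Package: permchip
Title: Diffusional Permeability of Endothelial Barriers from Microfluidic
    Time-Lapse Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the absolute diffusional permeability coefficient
    (P_d, cm/s) of an endothelial monolayer toward fluorescent tracers and
    nanoparticles from time-lapse fluorescence stacks acquired on two-channel
    microfluidic devices. Implements the ROI-based intensity analysis (lumen
    box, one-pixel interface line, gel box), lumen-filling detection,
    initial-slope and flux-matched permeability estimation, and focal-leak
    quality control. Ships a physics-based synthetic-data generator (1-D
    diffusion with a Robin membrane-flux boundary, EMCCD-like shot and read
    noise) with a closed-form analytic oracle, plus downstream statistics:
    condition summaries (mean and SEM), Student's t-tests, fold changes,
    size-selectivity tables and the tumor-to-normal permeability ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tiff,
    yaml,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
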