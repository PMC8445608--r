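Package: dcisim
Title: Hybrid Multiscale Agent-Based Simulation of Ductal Carcinoma in Situ
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional hybrid multiscale model of early ductal
    carcinoma in situ (DCIS) inside a mammary duct section. Discrete
    off-lattice cell agents with a stem/progenitor/differentiated hierarchy,
    estrogen-receptor phenotypes, density-induced quiescence and a
    hypoxia-necrosis-lysis-calcification cascade are bidirectionally coupled
    to continuum reaction-diffusion fields for oxygen, estrogen, amphiregulin
    (AREG) and FGF solved on a cylindrical duct domain. Includes procedural
    seeding of the mature duct bilayer and tumor-initiating-cell niche,
    biphasic (exponential-to-linear) growth segmentation, axial advance and
    calcification rate estimation, and local parameter sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
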