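Package: gliovasc
Title: Glioma-Vasculature Interplay Simulator with Go-or-Grow Phenotype Switching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates one-dimensional reaction-diffusion models of glioma
    invasion coupling oxygen-dependent migration/proliferation phenotype
    switching (Go-or-Grow), oxygen transport, and functional tumour
    vasculature subject to angiogenesis and vaso-occlusion. Provides a
    hierarchy of three model variants (Fisher-Kolmogorov, oxygen-coupled,
    fully vascular), method-of-lines integration with no-flux boundaries,
    tumour-invasion observables (front speed, infiltration width, effective
    diffusion and proliferation rates), and (D, b) parameter-plane sweep
    machinery that locates the critical proliferation rate and
    proliferation/diffusion ratio separating tumour responses to
    vaso-modulatory interventions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
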