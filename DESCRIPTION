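Package: pdvax
Title: Free-Boundary PDE Model of Combined Cancer Vaccine and Anti-PD-1 Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic model of tumor growth under combination immunotherapy with a
    GM-CSF-secreting cancer vaccine (GVAX) and a PD-1 checkpoint inhibitor. Implements
    the radially symmetric free-boundary reaction-advection-diffusion system coupling
    dendritic cells, CD4+ and CD8+ T cells, cancer cells, the cytokines IL-12 and IL-2,
    GM-CSF, PD-1/PD-L1 checkpoint kinetics and an anti-PD-1 drug; a fully implicit
    moving-mesh finite-difference solver; closed-form steady-state parameter
    calibration; dose-response efficacy and synergy maps with an optimal-dose curve;
    and Latin hypercube / partial rank correlation (PRCC) sensitivity analysis of the
    day-60 tumor radius.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lhs,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
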