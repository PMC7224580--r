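Package: ptmgeo
Title: Parameter Geography of Bistability in Two-Site Modification Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps the parameter geography of bistability in a two-site,
    sequential, distributive post-translational modification (PTM) system.
    The steady state of the reduced system is the solution set of a pair of
    bivariate quartic polynomials in the free-enzyme fractions; the package
    builds that system from eight non-dimensional parameters, finds all of
    its finite complex solutions by Sylvester-resultant elimination with
    Newton certification, and classifies each parameter point as
    monostable or bistable.  On top of the solver it provides independent
    logarithmic random (ILR) sampling of parameter boxes, Monte Carlo
    estimation of the bistable volume with central-limit confidence
    intervals, VEGAS adaptive importance sampling for enriching rare
    bistable sets, epsilon-graph spanning-forest connectivity analysis
    with nearest-neighbour refinement, K-fold visibility-ratio estimation,
    substrate-threshold scans, detection of "blinking" parameter points,
    and the product-rebinding tradeoff bound.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
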