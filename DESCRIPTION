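Package: toygold
Title: Metadynamics Re-Weighting and Peptide-Surface Adsorption Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for metadynamics simulations of peptide adsorption
    at solid-liquid interfaces: reconstruction of the history-dependent bias
    from deposited Gaussian hills, symmetrised adsorption free-energy profiles
    with asymmetry error bars, equilibration-period assignment by collective
    variable histogramming, three trajectory re-weighting schemes for unbiased
    ensemble averages, residue-surface contact probabilities with contact
    strength classes, and interfacial water structure metrics (vertical and
    lateral density, first-layer boundary, displaced-water counts). Ships a
    synthetic Langevin/toy-slab system with analytically known ground truth so
    the whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
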