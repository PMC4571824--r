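Package: tunnelfold
Title: Coarse-Grained Simulation and Single-Molecule Analysis of
    Cotranslational Folding in the Ribosome Exit Tunnel
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how small protein domains fold while still
    inside the ribosome exit tunnel. Provides a structure-based (Go-type)
    coarse-grained model of a nascent chain tethered at the peptidyl
    transferase center inside a repulsive tunnel scaffold, Langevin
    dynamics with temperature replica exchange, implicit-ligand stability
    calibration of the native-contact well depth, folded-state
    classification and probe-anchor distance distributions. Also
    implements the arrest-peptide force-profile statistic f_FL =
    I_FL/(I_FL + I_A) with replicate SEMs, peak location and Hill
    titration fits, and a two-state segmentation and dwell-time pipeline
    for single-ribosome inter-subunit FRET traces. Seeded synthetic-data
    generators for every input (toy native domain, toy tunnel, gel lanes,
    fluorescence traces) are first-class components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
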