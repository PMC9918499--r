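Package: nucdyn
Title: Nucleosome Dynamics Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nucleosomal DNA unwrapping, gyre gaping, histone core
    flexibility and histone tail-DNA interactions from molecular dynamics
    trajectories of nucleosomes. Provides dyad-centered base-pair coordinates
    and superhelical-location (SHL) bookkeeping, histone-core superposition and
    equilibration trimming, heavy-atom contact counting, Boltzmann-inversion
    free-energy profiles over unwrapped base pairs and two-dimensional
    collective-variable surfaces, RMSF flexibility analysis, and histone
    variant sequence analytics (H2A versus H2A.Z). A coarse-grained zipper
    model generator synthesizes pseudo-atom nucleosome trajectories with known
    ground truth so every analysis stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    signal,
    yaml,
    jsonlite,
    Rcpp,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
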