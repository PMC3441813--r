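Package: rhmap
Title: Radiation Hybrid Map Construction, Integration and Comparative Synteny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds radiation hybrid (RH) maps from hybrid-clone genotype
    vectors: two-point breakage/retention maximum-likelihood estimation and
    LOD-based group formation, multipoint marker ordering under a two-state
    retention Markov chain with centiray (cR) coordinates, integration with a
    genetic linkage map through shared microsatellites (including linkage-group
    merging and FISH-constrained orientation), comparative synteny against
    model genomes (conserved segments, ordered conserved segments, Oxford
    grids), and the cR/cM/kb calibration chain that converts an RH map into a
    physical size and genome coverage estimate. A seeded simulator generates
    RH panels, genetic maps and rearranged model-species anchor tables with
    known ground truth so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
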