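Package: sbsfold
Title: Strings-and-Binders Polymer Models of Chromatin Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained polymer-and-binder (strings-and-binders, SBS)
    Langevin molecular dynamics for chromatin loci, with the analysis suite
    used to study coil-globule phase behaviour and ensemble/single-molecule
    structure: contact maps and their comparison statistics (Pearson,
    genomic-distance-corrected Pearson, Spearman, contact-probability
    curves), single-molecule distance-map heterogeneity, inertia- and
    gyration-tensor shape descriptors (semi-axes, ellipticity, volumes),
    phase-diagram sweeps over binder concentration and affinity, and
    calibration of model units to physical nanometres and seconds.
    Includes generators for synthetic binding profiles and toy contact
    maps, trajectory input/output, and a one-call pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    tibble,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
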