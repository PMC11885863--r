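Package: roottrack
Title: Temporal Root System Architecture Phenotyping from Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies root system architecture (RSA) dynamics of vertically
    grown seedlings from time series of binary segmentation masks. Each frame
    is skeletonized and decomposed into one main root (MR) and a set of
    lateral roots (LRs); LRs are tracked across frames by their initiation
    position so that per-root trajectories carry stable, emergence-ordered
    labels. From the tracked decomposition the package computes the standard
    scalar feature catalogue (lengths, LR counts and densities, growth
    speeds, spectral features of the speeds, convex-hull geometry) together
    with two gravity-referenced lateral-root angles: the base-tip angle and
    the fixed-arc-length emergence angle. Cohort-level genotype comparison
    uses per-hour Mann-Whitney rank-sum tests with a both-lines significance
    flag, and whole-cohort superposition count maps. A parametric growth
    simulator with a gravitropic exponential bending law provides
    ground-truthed synthetic mask series for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    Rcpp,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
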