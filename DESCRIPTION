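Package: mukaxis
Title: Stochastic Loop-Extrusion Simulation and Quantitative Imaging Analytics
    for the MukBEF Chromosome Axial Core
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the Escherichia coli SMC complex MukBEF
    organizes the chromosome into an axial core. Provides an exact
    continuous-time Markov chain (Gillespie) simulator of MukBEF
    dimer-of-dimers loop extrusion on a discretized circular chromosome with
    optional MatP-mediated displacement from the replication-terminus region;
    analytics for simulated loop states (looped chromosome fraction,
    per-complex loop sizes, MukBEF cluster detection, locus-to-cluster
    distances with loops acting as shortcuts, force-directed layouts);
    single-molecule tracking analytics (track linking, apparent diffusion
    coefficients, bound-fraction classification, residency-time survival
    analysis with photobleaching correction); morphometrics of filamentous
    fluorescence structures (Otsu segmentation, centerline extraction,
    linear and circular core length, Gaussian-FWHM thickness, lengthwise
    compaction ratios); and ground-truthed synthetic data generators so that
    every analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
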