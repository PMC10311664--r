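Package: aeromorph
Title: Whole-Aerosol Morphology Analysis for Coarse-Grained Sea-Spray Particles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for droplet-in-vacuum molecular models of
    submicrometer sea-spray aerosol. Computes gyration-tensor shape
    descriptors (asphericity, relative shape anisotropy), density-based
    surfactant raft clustering with head-tail orientation features,
    minimum-volume bounding-ellipsoid fitting with equal-volume
    concentric-shell mass partitioning, shell-resolved water diffusion
    from mean squared displacement, and interfacial metrics (surface
    coverage, surface excess, raft curvature, atmospheric exposure).
    Includes a synthetic coarse-grained particle and trajectory generator
    that reproduces the published composition designs and provides ground
    truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph
Config/testthat/edition: 3
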