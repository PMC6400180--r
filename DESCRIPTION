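Package: spisort
Title: Diffraction-Pattern Classification and Reconstruction Evaluation
    for XFEL Single-Particle Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for sorting X-ray free-electron laser (XFEL)
    single-particle diffraction snapshots into single-hit and
    non-single-hit classes, and for evaluating the 3D models
    reconstructed from the selected patterns.  Implements a desk-scale
    pipeline: a synthetic diffraction-data generator for an icosahedral
    virus-like particle (single hits, interfering multi-particle hits,
    droplet/blank frames, Poisson photon noise), the detector
    preprocessing chain (pixel binning, Friedel bad-pixel repair,
    ADU-to-photon conversion, log scaling, mean normalization), three
    classifiers (semi-supervised graph cut with a total-variation Potts
    functional solved by a primal-dual algorithm, a 316-parameter
    convolutional neural network, and diffusion-map embedding with
    nearest-centroid labelling), consensus selection across
    classifiers, iterative phase retrieval (error reduction and
    difference map with a top-voxel support update), and model-quality
    metrics (radial profiles, shell R factors, Fourier shell
    correlation, phase-retrieval transfer function, orientation
    log-likelihoods with p-max analysis, and cross-section
    eccentricity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    rhdf5,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
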