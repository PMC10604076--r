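Package: swarmreader
Title: Multimodal Droplet-Particle Well Imaging and Swarm-Sensing Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for droplet immunoassays read out on a
    low-cost multimodal imager. Synthesizes high-dynamic-range (HDR)
    fluorescence images from exposure-bracketed 10-bit raw frames, registers
    bright-field and dark-field images to the HDR frame with phase correlation
    and a second-order radial chromatic-aberration model, detects
    particle-templated droplets independently in each modality with a
    Canny-based segmenter, fuses the per-modality masks under a convexity
    constraint, quantifies per-droplet fluorescence over PEG, droplet and
    combined regions of interest, and implements the swarm-sensing statistical
    layer: negative-control mu + 3 sigma thresholding, fraction of particles
    above threshold, standard-error-versus-n curves, one-tailed Welch tests,
    Monte Carlo subsampling of particle counts and dose-response/limit-of-
    detection summaries. Ships a ground-truthed synthetic well-image generator
    so the whole pipeline is testable without physical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    tiff,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
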