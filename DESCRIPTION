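Package: spectraclust
Title: Alignment-Free Clustering of DNA Sequences via Fourier Power Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters nucleotide sequences without alignment by mapping each
    sequence to a four-channel binary indicator signal (Voss representation),
    computing its power spectral density with the discrete Fourier transform,
    and partitioning the spectra with a multi-restart K-means using Euclidean
    distance. Includes a radial visualization that places cluster centroids
    around their common mean and each sequence around its centroid at its
    spectral distance, decomposition and reference-centroid validity
    analyses, a synthetic sequence-family generator for end-to-end testing,
    and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
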