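Package: dynamelt
Title: Dynamics-Informed Multigraph Learning of Protein Melting Temperatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds dynamics-informed graph representations of proteins from
    coarse-grained elastic-network normal modes and learns melting temperatures
    from them. Alpha-carbon anisotropic network models yield normal-mode
    spectra, from which three residue-pair coupling matrices are computed:
    co-directionality, coordination, and deformation. Seven thresholding
    schemes convert couplings into unweighted graphs that, together with
    contact and backbone edges, form multigraph samples. Graph feature
    extractors (single-graph convolution, per-dimension convolution, and a
    multi-dimensional graph convolutional aggregation with cross-dimension
    attention) feed a regression head that combines graph features with the
    organism's optimal growth temperature. Includes Laplacian node-centrality
    profiles for residue-level interpretation, a deterministic
    synthetic-structure generator for fully offline testing, paired-bootstrap
    model comparison, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
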