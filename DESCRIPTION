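Package: promspec
Title: Spectral Clustering of Promoter Sequences and Detection of Regular
    Tracts with the Harmonic Peyrard-Bishop Model
Version: 0.1.0
Authors@R:
    person("promspec", "developers", email = "promspec@example.org",
           role = c("aut", "cre"))
Description: Tools for the unsupervised structural analysis of promoter
    sequences. Promoters are clustered by whole-sequence similarity using
    affine-gap pairwise alignment (EMBOSS scoring conventions), a reshuffling
    null model to threshold the similarity graph, and normalized-Laplacian
    spectral clustering with eigengap model selection. Independently, regular
    sequence tracts (homogeneous, periodic and palindromic in the weak/strong
    binary code) are detected per promoter from the localization properties
    of the eigenvectors of the harmonic Peyrard-Bishop lattice Hessian.
    Downstream cataloguing covers TATA-box consensus scanning,
    position-resolved base composition and dinucleotide profiles, per-cluster
    regular-sequence catalogues, and overlap statistics against RepeatMasker
    or BED repeat annotations. A synthetic-promoter generator with planted
    ground truth supports testing and calibration at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
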