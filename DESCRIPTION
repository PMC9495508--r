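Package: hyperplace
Title: Hyperbolic Embedding of Gene Sequences for Phylogenetic Placement
    and Tree Updating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a map from aligned gene sequences into hyperbolic
    (Poincare ball or 'Loid/Lorentz model) or Euclidean space whose
    distances reproduce the leaf-to-leaf path distances of a backbone
    phylogeny. A small convolutional encoder composed with an exponential
    map is trained with a weighted relative-distance objective and
    alternating closed-form updates of a global scale (equivalently, the
    curvature). The learned distances place new query sequences onto the
    backbone by weighted least squares, and build hybrid distance
    matrices that extend the backbone into a fully resolved tree with
    external distance-based tools. Includes distortion and
    tree-comparison metrics and a synthetic benchmark generator (random
    species trees, NNI-discordant gene trees, Jukes-Cantor alignments).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
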