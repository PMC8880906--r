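Package: trefoilthemes
Title: Bridging Themes and Beta-Trefoil-Like Structural Motifs Between
    Protein Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-track evolutionary analysis of fragment sharing between
    the beta-trefoil fold and other protein domain lineages. The sequence
    track cuts sliding four-beta-strand windows from master domains, builds
    profile hidden Markov models from filtered multiple sequence alignments,
    searches domain databases with simulation-calibrated E-values, and
    confirms hits with a shuffle/extreme-value-distribution significance
    test, aggregating results into bridging-theme networks and metamorphism
    statistics. The structure track searches target structures for the
    beta-trefoil-like motif with a motif-length-normalized TM-score and
    characterizes the hallmark conserved-water hydrogen-bond geometry,
    hydrophobic clamp, and proline-mediated dry variants. A synthetic-data
    module generates sequence families with planted shared segments and
    idealized four-strand structures with planted water geometry so that
    every stage is testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
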