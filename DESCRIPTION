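Package: SpaceTimeFold
Title: Nussinov RNA Folding with Space-Time Tiled Dynamic Programming
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-base-pairing RNA secondary structure prediction
    (Nussinov's dynamic program) together with a space-time tiling of its
    triply nested loop: space bands over the row index and the anti-diagonal,
    time slices over the split index, and a skewed wavefront schedule whose
    tiles execute in parallel. Includes the dependence-analysis machinery
    needed to prove the tiling valid on concrete problem sizes: brute-force
    dependence extraction for the loop nest, global distance vectors,
    exhaustive schedule validation, and a free-schedule (earliest-start)
    laboratory over box iteration spaces with constant distance vectors.
    Provides reference, cache-friendly transpose, and tiled folding engines,
    traceback to dot-bracket, FASTA input, a random-strand generator, and a
    reproducible benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, StructuralPrediction, FoldingAndStructure, RNA
RoxygenNote: 7.3.3
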