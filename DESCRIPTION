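Package: neurautomata
Title: Neural Automata, Godel Encodings and Recoding-Invariant Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for embedding symbolic computation into neural phase spaces.
    Symbol sequences are mapped to the unit interval by Godel encodings (exact
    rational arithmetic throughout), dotted-sequence rewriting machines
    (versatile shifts, including top-down context-free-grammar recognizers) are
    compiled into nonlinear dynamical automata (piecewise affine maps on the
    unit square) and further into modular recurrent neural networks. The
    package implements patterns of equality, orbit enumeration under Godel
    recodings, invariant partitions of the interval and the unit square, and
    macroscopic observables (Amari mean activity, harmony, dissimilarity, and
    recoding-invariant step observables) together with a verification harness
    for invariance under the blank-fixing recoding symmetry group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
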