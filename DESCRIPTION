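Package: bncana
Title: Canalization and Control in Boolean Network Models of Biochemical Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dynamical redundancy (canalization) and controllability
    in Boolean network models of gene regulation and biochemical signaling.
    Reduces automata look-up tables to prime-implicant wildcard schemata
    (Quine-McCluskey) and two-symbol schemata capturing permutation redundancy;
    computes input redundancy, effective connectivity and input symmetry at the
    node and per-input level; builds effective graphs, canalizing maps and the
    dynamics canalizing map; enumerates synchronous attractors from the state
    transition graph; and measures driver-variable control via controlled state
    transition graphs, controlled attractor graphs, structural controllability
    and minimum dominating sets. Ships transcriptions of classic regulatory
    network models, including the Arabidopsis thaliana floral organ network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
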