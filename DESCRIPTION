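Package: paleoasr
Title: Ancestral State Reconstruction of Discrete Skeletal Characters on
    Paleontological Supertrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing the evolutionary history of discrete
    osteological characters on composite fossil phylogenies. Assembles
    species-level supertrees by grafting published source cladograms onto a
    backbone at shared landmark taxa, timescales the result from
    stratigraphic first and last appearance data with a minimum branch
    length correction, converts specimen-level evidence tables (rib counts,
    attachment scars, preserved processes) into multi-state character
    codings with explicit uncertainty, and infers ancestral states by
    Sankoff parsimony, Mk maximum likelihood with exact marginal
    reconstruction, and Bayesian Markov chain Monte Carlo. Includes a
    birth-death and Mk forward simulator with a probabilistic observation
    layer for validating every stage, and an orchestrator that runs the
    full coding-by-method-by-branch-length analysis grid and reports
    clade-level state probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
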