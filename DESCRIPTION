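Package: herbnet
Title: Network-Pharmacology Candidate-Target Inference for Multi-Herb Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a network-pharmacology inference chain for dissecting
    the action of multi-herb formulas on a disease model: differential
    expression screening of a five-arm (control, disease model, full formula,
    two single-herb-deletion) design, construction of score-thresholded
    gene-gene interaction networks, two-stage topological hub selection
    (degree rule, then joint degree/betweenness/closeness/k-coreness rule),
    chemical-similarity transfer of drug-target annotations to formula
    compounds, hypergeometric pathway over-representation with
    Benjamini-Hochberg control, treatment-reversal classification, and
    herb-pair core-gene intersection. Ships a synthetic-data generator that
    plants disease genes, a hub module, an enriched pathway, and
    target-annotated compound analogues, so the whole pipeline is testable
    end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
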