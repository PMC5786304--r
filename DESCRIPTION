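Package: treeddi
Title: Drug-Drug Interaction Extraction with a Binary Tree-LSTM
Version: 0.1.0
Authors@R: person("DDI", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Extracts drug-drug interactions (DDI) from sentence-level
    candidate drug pairs with a recursive neural network over binary
    constituency parse trees. Implements corpus ingestion for SemEval
    DDIExtraction-style XML, preprocessing (drug anonymization, number
    masking, negative-instance filtering, deduplication), bracketed
    parse-tree reading and binarization, position and subtree-containment
    input features, a child-pair tree-LSTM classifier trained with Adam
    and recurrent dropout, one-stage and two-stage classification with a
    logit-sum ensemble, micro-averaged F1 evaluation with
    filtered-positive accounting, and a synthetic corpus generator so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
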