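Package: filmSens
Title: Conditional Modeling of Chemical Sensitivity from Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cellular viability from a basal transcriptome, a compound
    structure, and a concentration with a feature-wise linear modulation (FiLM)
    conditional neural network, and analyses the resulting in-silico screens:
    dose-response quality control and log-logistic fitting with IC50/AUC/ED50
    pharmacodynamics, integrated-gradients feature attribution with control-model
    soundness checks, and attribution-based interpretation (clustering, adjusted
    mutual information, differential attribution, protein-interaction module
    analysis). Ships a synthetic pharmacogenomics generator with planted ground
    truth so every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
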