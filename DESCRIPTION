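Package: epimotif
Title: Transcription Factor Binding Region Prediction from Motifs and
    Modified Nucleosome Positions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts transcription factor binding regions by fusing
    position weight matrix (PWM) motif scanning over 1-kb genomic bins
    with two features derived from the positions of histone-modified
    nucleosomes: the distance to the nearest modified nucleosome (MNN)
    and the count of modified nucleosomes flanking a region's center
    (MNO). A from-scratch logistic regression classifier maps the
    epigenetic features to a binding probability, which is combined
    multiplicatively with the scaled PWM score. Includes ROC/AUC
    evaluation, nucleosome-distribution profiling around binding sites,
    and a synthetic-data generator that emulates genome, binding-site
    and nucleosome-track inputs with bimodal active-mark enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
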