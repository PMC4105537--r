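Package: pubnet
Title: Multi-Tissue Co-Expression Network Analysis of the Pubertal Transition
Version: 0.1.0
Authors@R:
    person("Pipeline", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-tissue RNA-Seq analyses of a two-state
    (pre- versus post-pubertal) experimental design: mixed-model
    normalization of log2 RPKM expression via EM-REML and BLUP,
    differential expression through a two-component normal mixture with
    an empirical null, Shannon-entropy tissue-specificity scoring with a
    permutation-derived threshold, regulatory impact factor (RIF) scoring
    of transcription factors, partial-correlation-and-information-theory
    (PCIT) co-expression network reconstruction per physiological state,
    network comparison and exhaustive transcription-factor trio
    expansion, and integration of GWAS association tables with
    expression evidence. Includes a synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
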