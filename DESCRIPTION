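Package: adrminer
Title: Mining Adverse Drug Reactions from Online Healthcare Forum Messages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Text-mining toolkit for pharmacovigilance on patient forum text.
    Classifies forum messages as containing adverse drug reaction (ADR)
    reports and extracts (drug, causal keyword, side-effect) relations with a
    four-state discrete hidden Markov model (supervised initialization,
    Baum-Welch refinement, Viterbi decoding), alongside a drug/side-effect
    co-occurrence baseline. Includes a staged, toggleable text-processing
    pipeline (HTML stripping, case/punctuation/numeral normalization,
    stop-word filtering, lexicon phrase matching), confusion-matrix metrics
    with seeded k-fold cross-validation and ablation harnesses, corpus-level
    side-effect aggregation with known-versus-novel splitting, and a seeded
    generator of annotated synthetic forum corpora for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stringi,
    withr,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
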