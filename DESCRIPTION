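Package: kinsig
Title: Kinase Co-Expression Signatures and Survival Biomarker Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of prognostic gene signatures built from
    genes co-expressed with B-cell-receptor signaling kinases. Implements
    robust biweight midcorrelation, multi-dataset consensus gene selection
    with an anchor kinase, Cox proportional-hazards prognostic indices with
    median-split risk groups, hazard ratios, Kaplan-Meier curves, log-rank
    tests, leave-one-out gene contributions, multivariate clinical models,
    qPCR delta-Ct relative expression with stage contrasts, enzyme-activity
    scoring from kinetic traces, and Chou-Talalay median-effect combination
    indices. A synthetic-data module generates every input with planted
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
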