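Package: oomech
Title: Oocyte Biomechanics from Micropipette Aspiration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the viscoelastic properties of human oocytes
    from micropipette-aspiration recordings and relating them to preimplantation
    developmental outcomes. Provides a synthetic-data generator (creep curves,
    rendered aspiration frame stacks, patient-structured outcome cohorts with
    known ground truth), automated tracking of the aspirated zona pellucida in
    image stacks, fitting of a modified Zener (standard linear solid plus
    series dashpot) creep model by sum-of-squared-error minimisation, a
    patient-grouped support-vector-machine classifier of usable-blastocyst
    formation with greedy forward feature selection, Fleiss' kappa for
    multi-rater agreement, and chi-square safety comparisons of measured
    versus control oocytes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    pROC,
    jsonlite,
    png,
    rlang
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
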