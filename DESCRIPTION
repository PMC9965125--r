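Package: clickqsar
Title: QSAR Modeling of NSAID-Triazole Click Conjugates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantitative structure-activity
    relationship (QSAR) analysis of non-steroidal anti-inflammatory drug
    (NSAID) conjugates built by copper-catalysed azide-alkyne click
    chemistry. Implements charged partial surface area (CPSA) descriptors
    from empirical partial charges and solvent-accessible surface areas,
    frontier-orbital reactivity and energy descriptors from an extended
    Hueckel molecular-orbital engine, best multilinear regression with
    leave-one-out and leave-many-out cross-validation, in-silico
    enumeration of propargyl-ester/triazole conjugate libraries validated
    against high-resolution mass spectrometry formulas, and the potency
    and cyclooxygenase selectivity-index arithmetic of the underlying
    pharmacology tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
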