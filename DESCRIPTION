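Package: panicleBSA
Title: Bulked-Segregant Mapping of EMS Mutants and Spikelet
    Expression-Pattern Target Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale pipeline for forward-genetic mapping of
    EMS-induced mutants in sorghum and for nominating downstream
    regulatory targets from staged spikelet expression profiles.
    Implements EMS-aware variant filtering (quality, depth windows,
    homozygosity, canonical G/C-to-A/T transitions, parental background
    subtraction), variant consequence annotation against gene models,
    bulk-segregant intersection mapping with allelic-series collection,
    F2 co-segregation statistics (Fisher exact, 3:1 goodness of fit),
    a three-rule expression-pattern classifier for candidate targets of
    a spikelet-suppressing TCP factor, and hypergeometric GO
    over-representation with Benjamini-Yekutieli FDR control. Ships a
    seeded simulator that generates every input with a ground-truth
    manifest for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
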