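Package: chromlink
Title: Integration of lncRNA Histone-Modification Peaks with RNA-Chromatin Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating a database of lncRNA-correlated histone-modification
    peaks with a database of experimentally detected RNA-chromatin contacts.
    Reconciles gene annotations across GENCODE versions into a one-to-one
    correspondence table (coordinate overlap, Jaccard index, name and identifier
    matching with a name fallback), decides per peak whether it is confirmed by a
    window-extended contact of the same lncRNA, runs sign-stratified one-sided
    Fisher's exact tests per lncRNA-histone mark pair with a support-proportion
    filter, builds cross-database navigation URLs, and generates synthetic
    annotation/peak/contact data with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
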