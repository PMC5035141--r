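Package: ppescreen
Title: Screening for Direct Transcription-Factor Targets in Pre-Placodal Ectoderm Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Analysis pipeline for hormone-inducible transcription-factor
    target screens in Xenopus pre-placodal ectoderm explants. Starting from
    FPKM expression tables of a factorial design (Six1/Eya1/Six1+Eya1 injection
    groups crossed with cycloheximide vs cycloheximide+dexamethasone
    treatment), the package computes per-group induction fold changes, applies
    a three-criterion differential-expression filter cascade with an
    un-injected DEX-artifact control, partitions differentially expressed
    genes across treatment groups into Venn regions and co-regulation classes,
    re-tests pooled (merged-replicate) designs with Welch tests and
    Benjamini-Hochberg FDR control, scores gene-set enrichment with Fisher and
    EASE statistics, prioritises well-supported candidate regulators, and
    cross-validates induction by delta-delta-Ct qPCR quantification. A
    synthetic-data generator with planted target classes provides ground truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
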