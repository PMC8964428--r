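Package: cdprx
Title: Pathway-Level In Silico Drug Prescription Across Cancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores pathway dysregulation in paired tumor/normal cohorts by
    gene set enrichment analysis (the cancer NES matrix, CNS), classifies
    pathway modes of action by consensus clustering, quantifies pan-cancer
    generality of dysregulation with a rank-based score, identifies
    prognostic pathways by an optimal-cutoff log-rank scan over single-sample
    (ssGSEA) pathway activation scores, scores the potency of perturbation
    (drug) profiles to reverse pathway dysregulation (PNS and the
    prescription score PS = CNS - PNS), and assembles the resulting
    drug-pathway-cancer triplet networks. Includes SAM-style moderated
    differential expression with permutation FDR and a synthetic-data
    generator emulating paired cohorts, survival outcomes tied to pathway
    activation, and perturbation libraries with planted reverser drugs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
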