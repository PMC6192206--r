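Package: psmEnsemble
Title: Ensemble Scoring and Supervised Filtering of Peptide-Spectrum Matches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A shotgun-proteomics database search engine and filtering
    pipeline aimed at metaproteomics, where protein databases are large and
    incomplete. Every MS2 spectrum is scored against candidate peptides with
    three diverse scoring functions - a multivariate hypergeometric score
    (MVH), a fast binned cross-correlation (Xcorr) and a weighted dot
    product (WDP) - in a two-tier scheme. Peptide-spectrum matches are then
    filtered with a supervised classifier trained on unanimous PSMs against
    decoy PSMs from a training split of reversed-decoy proteins, with false
    discovery rates estimated from the held-out decoy split. Accepted PSMs
    are assembled into peptide and protein-group identifications. Includes
    a synthetic FASTA/MGF fixture generator with ground-truth labels so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    Biostrings,
    data.table,
    glmnet,
    randomForest,
    rpart,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
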