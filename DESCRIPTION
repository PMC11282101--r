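Package: metsubtype
Title: Molecular Subtyping of MET Exon 14 Skipping NSCLC from Targeted
    RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for transcriptomic subtype discovery and
    classification in MET exon 14 skipping (METex14) non-small cell lung
    cancer. Provides per-sample rank-based pathway enrichment scoring,
    consensus k-means clustering with CDF/delta-AUC model-order selection,
    subtype characterization (moderated-t differential expression,
    marker-mean tumor-microenvironment signatures, somatic variant
    filtering, non-negative mutational-signature refitting, Kaplan-Meier /
    log-rank / Cox survival association), and an odds-ratio-screened
    lasso-multinomial subtype classifier with repeated cross-validation.
    Includes a synthetic cohort generator emulating the assumed data
    structure (four pathway-programmed subtypes, subtype-linked survival
    and METex14 variant allele frequency) plus in-silico RT-PCR utilities
    for the exon-skipping amplicon-size check.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
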