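Package: mirsig
Title: Cross-Study miRNA Deregulation Signatures with Harmonized Identifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving and comparing microRNA differential-expression
    signatures across heterogeneous studies of papillary thyroid carcinoma and
    similar tumor/normal designs. Provides miRBase-style nomenclature
    harmonization to univocal mature accessions (MIMAT), signature calling from
    log2 expression matrices with detection, fold-change and Benjamini-Hochberg
    FDR rules, TCGA-style isoform read aggregation with reads-per-million
    normalization and nonparametric group testing, a vote-counting study-miRNA
    meta-analysis matrix with frequency scores, concordant multi-dataset
    signature intersection, Pearson/average-linkage hierarchical clustering
    with one-sided Fisher cluster-enrichment tests, and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
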