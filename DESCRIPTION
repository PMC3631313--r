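Package: glioburden
Title: Case-Control Driver-Gene Burden Testing and Methylation Consensus
    Clustering for Glioma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering candidate driver genes in tumour exome
    cohorts lacking matched normals: private-variant filtering against
    population databases and control exomes, per-gene case-control carrier
    burden testing with an exact hypergeometric test and Benjamini-Hochberg
    false-discovery-rate control (including a truncating-only scan),
    stratified mutation-frequency tables with grade, location and
    mutual-exclusivity association tests, consensus k-means clustering of
    450K-style methylation beta matrices with CDF/delta-area model selection,
    and densitometry-based histone-mark quantification. Includes synthetic
    cohort and beta-matrix generators with known ground truth for validation.
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
    mclust,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
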