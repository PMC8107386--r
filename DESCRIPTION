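Package: agnep
Title: Agglomerative Nesting of Phenotypes for Multi-Phenotype GWAS
Version: 0.1.0
Authors@R:
    person("AGNEP", "Developers", email = "agnep@example.org", role = c("aut", "cre"))
Description: Joint analysis of multiple correlated phenotypes in genome-wide
    association studies. Phenotypes are grouped by agglomerative nesting
    (single-linkage hierarchical clustering), the number of clusters is chosen
    by the maximum mean silhouette coefficient, each cluster is reduced to
    representative phenotypes (mean, median, or top principal components under
    a cumulative explained-variance rule), and every genetic variant is tested
    against the representatives with a per-variant MANOVA (Wilks' lambda).
    Includes a factor-model simulator of correlated phenotypes with known
    causal variants, FDR-based power evaluation, permutation significance
    thresholds, and readers/writers for PLINK bed/bim/fam and delimited
    dosage/phenotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
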