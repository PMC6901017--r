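Package: chemgenomics
Title: Chemical-Genomic Screen Analysis Across Genetic Backgrounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for colony-array chemical-genomic screens of
    gene-deletion libraries in multiple genetic backgrounds. Normalizes
    colony-size plates (spatial surface and border corrections, quality
    control), computes moderated S-scores per gene and condition,
    quantile-normalizes and calls significant growth phenotypes at a given
    false discovery rate, and detects significant differences in deletion
    phenotypes between strains with a sliding-window empirical null.
    Downstream summaries include phenotype conservation fractions,
    per-gene exclusiveness, loss-of-function gene-disruption (burden)
    scores from SIFT/FoldX/nonsense evidence, association-hit overlap with
    knockout phenotypes, and reproducibility and functional benchmarks.
    A synthetic-data generator with known ground truth supports testing of
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
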