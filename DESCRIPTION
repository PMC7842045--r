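Package: methcorr
Title: Infer Gene Expression from DNA Methylation with Expression-Correlated CpG Sites
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains per-gene regression models that infer RNA expression from
    Illumina 450K/EPIC DNA methylation beta-values and applies them to new
    methylation profiles, including FFPE material. Genome-wide Spearman
    screening in two discovery sets identifies up to 100 positively and 100
    negatively expression-correlated CpG sites per gene; their beta-values are
    summarised into a per-gene MethCORR score, which is mapped to expression by
    polynomial regression selected via repeated 10-fold cross-validation.
    Includes a seeded synthetic cohort generator with known ground truth for
    benchmarking every pipeline stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
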