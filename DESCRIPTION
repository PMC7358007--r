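Package: tcdosage
Title: Dosage Imbalance, Deletion Mapping and Mosaicism Analysis for
    Transchromosomic Trisomy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational characterization of transchromosomic (trisomic)
    mouse models carrying a human chromosome arm on an artificial-chromosome
    vector. Provides coverage-based deletion mapping on the single-copy
    transchromosome from binned read depth, cross-species gene-dosage
    accounting (human transgene plus mouse ortholog relative to euploid
    expression, in FPKM), per-tissue mosaicism/retention estimation with
    Wilson score intervals, water-maze probe-trial chance-level geometry and
    the retained-memory statistic, plus a synthetic-data generator with
    planted ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
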