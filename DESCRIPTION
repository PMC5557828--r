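Package: fragratio
Title: Pool-Seq Fragment-Ratio Detection of Y-Linked Scaffolds and Sex Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies putative Y-linked scaffolds and candidate male-specific
    marker fragments from male/female pooled whole-genome resequencing depth
    over a softmasked male reference assembly. Splits softmasked scaffolds into
    unmasked fragments, ingests per-fragment mapped-read counts for the two
    pools (samtools idxstats format or BAM), computes the normalized
    female:male fragment-ratio statistic, tests per-scaffold enrichment of
    Y-candidate fragments with an upper-tail hypergeometric test, and applies a
    female-assembly homology filter to nominate marker candidates. Ships a
    seeded simulator of pooled counts under the XX/XY copy-number model so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
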