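Package: chipsad
Title: Transcript Segmentation, Alignment and Classification for High-Density Bacterial Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segments high-density (tiling and non-tiling) bacterial
    transcriptome array signal into transcript units using a sliding/expanding
    window change-point detector built on a SAM-style generalized t-statistic
    and Hodges-Lehmann pseudomedian smoothing; aligns transcript units across
    multiple experiments into weighted consensus transcripts via interval
    overlap graphs; and classifies the resulting units against GenBank ORF
    annotation into ORFs, operons, antisense RNAs, UTRs and intergenic RNAs.
    Includes a fully deterministic synthetic-data generator for probe layouts,
    piecewise-constant transcript signal and toy annotations, plus a
    command-line front end for the whole pipeline.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
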