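Package: ztrscan
Title: Detection and Characterization of Z-to-W Transposed Regions from
    Sex-Stratified Sequencing Summaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers Z-to-W transposed regions (ZTRs) on female-heterogametic
    (ZW) sex chromosomes from per-site read-depth tables and per-sample variant
    calls, by combining normalized window coverage with sex-stratified SNP
    density signatures. A ZTR is a segment recently copied from the Z onto the
    highly degenerated W chromosome; because the W-derived reads still co-map
    to the Z reference, females show autosome-like coverage together with a
    female-specific excess of heterozygous sites. The package classifies
    windows into ZTR, pseudoautosomal, Z-linked duplication and hemizygous-Z
    states, reconstructs the W-linked pseudo-sequence by substituting female
    variants into the Z reference with full indel coordinate accounting, calls
    W-deletions and per-gene fates (deleted, partially deleted, pseudogenized
    or intact), estimates branch-specific dN/dS by Nei-Gojobori counting with
    outgroup polarization, ranks genes by haploinsufficiency percentile, and
    profiles replicate-averaged expression with gonad-bias flagging. A
    seed-deterministic synthetic-data generator with planted truth supports
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
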