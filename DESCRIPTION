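Package: igallele
Title: Novel IGHV Germline Allele Prediction from IgM Repertoires with
    Genomic DNA Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts undocumented (novel) immunoglobulin heavy-chain
    V-gene germline alleles from bulk IgM antibody repertoire sequencing
    and validates them against targeted genomic DNA amplicon reads.
    Unique IgM sequences are assigned to their best-matched reference
    germline alleles, per-position substitution frequencies are profiled,
    and recurrent identical mismatches passing prevalence and discordance
    thresholds are emitted as candidate novel alleles with
    IMGT-convention names.  Candidates are confirmed by exact-match read
    tallies in non-B-cell genomic DNA, with copy-number-variant and
    gene-deletion flagging.  Includes a synthetic-data generator for
    diploid genotypes (0-4 copies per gene), low-rate somatic
    hypermutation with hotspots, and amplicon reads, so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
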