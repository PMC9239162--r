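Package: expevo
Title: Evolution of Developmental Gene Expression on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative developmental-transcriptomics toolkit for
    single-copy ortholog clusters (SCOGs) profiled across developmental
    stages in several species. Calls actively transcribed genes by
    z-transformed RPKM (zRPKM) density fitting, reconstructs ancestral
    stage-to-stage expression fold changes under Brownian motion on a
    rooted species phylogeny by maximum likelihood, ranks genes by
    fold-change differential (FCD) between an extant species and an
    inferred ancestor, quantifies expression divergence of ortholog
    clusters as averaged pairwise Euclidean distance between relative
    stage profiles, and bins genes into phylostratigraphic age classes.
    Ships a synthetic-data generator that emulates the assumed
    data-generating process (Brownian fold-change evolution with planted
    lineage-specific activation shifts, silent genes, and Poisson count
    noise) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
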