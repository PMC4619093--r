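Package: gmrsdkit
Title: Comparative Genomics of the GmrSD Family of Type IV Restriction Enzymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative-genomics analysis of the GmrSD family of
    modification-dependent (Type IV) restriction enzymes and, more generally,
    of two-domain defense systems that occur both as domain fusions and as
    separately encoded partner proteins. Provides domain-architecture
    classification from filtered domain-hit tables (GmrS-only, GmrD-only,
    double-domain), per-genome inventories and single-domain pairing into
    double-domain-like merged sequences; multiple-alignment merging
    bookkeeping, per-column conservation profiling and degenerate-motif
    compilation and scanning; genomic-neighborhood (defense-island)
    enrichment statistics based on Bonferroni-adjusted two-proportion
    confidence intervals; and a tanglegram-style coevolution pipeline with
    support-based split collapsing, counterpart pruning and Robinson-Foulds
    congruence. A synthetic-data module generates annotated genomes, protein
    families and tree pairs with known planted structure for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
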