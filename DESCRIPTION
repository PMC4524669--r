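Package: dysgenTE
Title: Transposable-Element and piRNA Analytics for Hybrid Dysgenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing intraspecific hybrid dysgenesis driven
    by divergence in transposable-element (TE) landscapes, modelled on the
    Drosophila virilis inducer/reactive strain system. Provides strain-level
    TE copy-number profiling from short-read mappings with a read-pileup
    homogeneity (age) statistic and an invasion-scenario classifier; small-RNA
    size classing with structural-RNA filtering, ping-pong signature metrics
    (percent ping-pong, non-redundant pair densities, 1U/10A biases) and
    row z-score matrices; genic piRNA targeting analysis (CDS densities,
    sense/antisense partition, exon/intron contrasts, ChIP IP:Input
    enrichment); expression analytics (RPKM, pseudocounted folds, low-count
    filters, allele-specific SNP counting, a six-way TE typology); and
    maternal-protection genetics (pseudo-diploid ancestry painting, induction
    log-odds, single-marker QTL with permutation thresholds, candidate-TE
    elimination). A synthetic-data module generates every input with planted,
    recoverable parameters so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
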