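Package: paleovar
Title: Evolutionary Origin of Clinical Variants via Cross-Species Alignment and Ancient Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to trace the evolutionary origin of clinically classified
    human variants (pathogenic, benign, uncertain) along two complementary
    routes: cross-species allele sharing extracted from multiple-genome
    alignment (MAF) blocks over a fixed vertebrate phylogeny, and detection of
    modern pathogenic variants in ancient-genome read data with
    postmortem-deamination profiling, quality rescaling, pileup calling and
    terminal-damage filtering. Includes HGVS cDNA/genomic coordinate
    conversion against transcript models, a minimal variant-effect
    classifier, clade-level nonparametric statistics with multiple-testing
    correction, and a fully deterministic synthetic-data generator (phylogeny,
    alignments with planted sharing, ClinVar-like catalogs, damaged ancient
    reads with truth sets) so the whole pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
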