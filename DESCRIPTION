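Package: shoremap
Title: Tile-Based Integration of DNMT Binding, Methylome Segmentation and
    Bivalent CpG Island Shores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide maps of de novo DNA
    methyltransferase (DNMT3A1/DNMT3A2/DNMT3B) binding in relation to the
    methylome. Partitions a genome into fixed-width tiles, computes
    pseudocount-regularized log2 ChIP enrichments over input, calls bound
    tiles with a negative-binomial test and partitions calls into exclusive
    sets, segments per-CpG bisulfite calls into unmethylated, low-methylated
    and fully methylated regions (UMR/LMR/FMR), classifies promoter CpG
    islands by methylation and H3K4me3/H3K27me3 bivalency, defines island
    shores and oriented UMR borders, and builds anchored meta-profiles with
    k-means signal clustering. Ships a seeded synthetic-genome generator
    that plants the expected structure (DNMT3A1 at methylated shores of
    bivalent CpG islands, 5-hmC at UMR borders) for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
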