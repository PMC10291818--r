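Package: polyhekit
Title: Subgenome Painting, Homoeologous Exchange Detection and Molecular
    Dating for Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing allotetraploid genomes with sequenced
    diploid progenitors: parent-of-origin classification of sequencing
    reads (competitive primary mapping for DNA, diagnostic-variant
    likelihoods for RNA), windowed subgenome painting and detection of
    homoeologous exchange (HE) blocks, breadth-of-coverage gene
    presence/absence and HE-gene calling, read-depth segmentation of
    large copy-number variants with split-read breakpoint refinement,
    Nei-Gojobori (1986) synonymous divergence and LTR repeat-pair
    divergence with conversion to insertion/divergence times via
    T = K/(2*mu), and subgenome bias statistics (directional chi-square,
    homoeolog count matrices, genome-wide Wilcoxon expression-bias test).
    Includes a deterministic synthetic allotetraploid generator (diverged
    parents, LTR bursts of known age, HE segments, per-sample gene
    deletions and CNVs, paired-end reads) and a minimal exact-seed read
    mapper so the full pipeline runs and is testable without external
    binaries or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
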