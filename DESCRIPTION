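Package: covscan
Title: Sequence-to-Coverage Modeling with Selective State-Space, Long-Convolution and Attention Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Building blocks and a desk-scale training pipeline for deep
    models that predict binned read-coverage tracks (RNA-seq, CAGE, DNase)
    from DNA sequence. Implements bidirectional selective state-space
    (Mamba-style) layers with a parallel associative scan, implicit
    long-convolution (Hyena-style) layers with SIREN-generated FFT kernels
    and a 1/L initialization rule, chunked multi-head attention with
    rotary or threshold-basis relative positional encodings, a U-Net
    pool/upsample wrapper, a composite Poisson-multinomial coverage loss,
    reverse-complement and shift augmentation with strand-paired track
    exchange, an Adam training loop with warm-up and two-level gradient
    clipping, a seeded synthetic regulatory-genome generator with planted
    motifs and known variant effects, and a downstream variant-effect
    scoring pipeline with a random-forest SNP classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    vcfR
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
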