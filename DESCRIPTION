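Package: exonDSP
Title: Digital Signal Processing Methods for Period-3 Exon Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Locates protein-coding regions (exons) in eukaryotic DNA by
    exploiting the period-3 spectral property of codon structure. Implements
    sliding-window DFT exon tracks over binary indicator sequences and the
    EIIP (electron-ion interaction pseudopotential) numeric mapping,
    narrowband IIR filtering of indicator channels with an all-pass-derived
    anti-notch design and a single peaking design, a reduced-computation
    single-channel variant, single-level Haar wavelet denoising of exon
    power tracks, half-power exon calling, evaluation against reference
    annotations, and a seeded synthetic-genome generator with planted
    period-3 exons for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Software, GenePrediction
RoxygenNote: 7.3.3
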