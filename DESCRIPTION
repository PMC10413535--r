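Package: covviz
Title: Visualize and Annotate Genome and Protein Coverage Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A layered grammar for genome coverage visualization across
    multi-sample, multi-omics sequencing experiments. Reads coverage signal
    from BAM, BigWig, BedGraph and TSV inputs with region-subset loading,
    normalizes binned read counts (CPM, RPKM, BPM, RPGC), builds consensus
    peaks from replicate peak sets by Fisher combination of p-values, and
    composes annotation layers (GC content, base frequency and SNV, amino
    acid frames, gene and transcript models, peaks, ideograms, contact maps,
    links, features, and mass-spectrometry protein coverage) over coverage
    panels with a '+' operator. Figures render to PDF, SVG or PNG through
    'ggplot2' and 'patchwork'. Includes a deterministic synthetic-data
    generator and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    grid,
    ggplot2,
    patchwork,
    rlang,
    yaml,
    jsonlite,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
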