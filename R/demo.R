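# End-to-end demo bundle: every input format the package reads, generated
# synthetically, plus declarative plot configs and a ground-truth manifest.

#' Generate a complete demo dataset
#'
#' Builds, under one directory: a reference FASTA (+ index), a WGS-style
#' BAM with a planted 100%-VAF T-to-A SNV, a ChIP/input BAM pair with
#' enriched peaks, a spliced RNA-seq-style BAM, a GTF of gene models,
#' replicate narrowPeak sets with a planned consensus subset, a cytoband
#' file, a dense contact-matrix TSV, a protein FASTA + peptide TSV, link
#' anchors, plot configuration files (`genome.yaml`, `protein.yaml`) and a
#' JSON manifest recording the ground truth every file was generated from.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; all outputs are deterministic in it.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
make_demo_bundle <- function(outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  chrom <- "chrSim"
  glen <- 50000
  reg <- region(chrom, 10000, 20000)

  fasta <- p("reference.fa")
  simulate_reference(fasta, chrom = chrom, length = glen, gc = 0.45,
                     gc_windows = data.frame(start = 14000, end = 16000,
                                             gc = 0.7),
                     seed = seed)

  # WGS: uniform coverage + planted SNV (T -> A at 100% VAF)
  ref <- read_reference_sequence(fasta, region(chrom, 0, glen))
  snv_pos <- 14999 + match("T", ref[15000:15200]) - 1  # a real T near 15k
  snv <- list(position = snv_pos, alt = "A", vaf = 1.0)
  simulate_alignments(p("wgs.bam"), fasta, region(chrom, 0, glen),
                      n_reads = 10000, read_length = 100, snv = snv,
                      sample = "wgs", seed = seed)

  # ChIP + input pair: enrichment only in ChIP
  chip_peaks <- data.frame(start = c(12000, 16500), end = c(12600, 17100),
                           enrichment = 30)
  simulate_alignments(p("chip.bam"), fasta, region(chrom, 0, glen),
                      n_reads = 3000, read_length = 80,
                      profile = "peaks", peaks = chip_peaks,
                      sample = "chip", seed = seed + 1)
  simulate_alignments(p("input.bam"), fasta, region(chrom, 0, glen),
                      n_reads = 3000, read_length = 80, sample = "input",
                      seed = seed + 2)

  # RNA-seq: spliced over gene 1's exons
  genes <- simulate_gene_models(p("genes.gtf"), reg, n_genes = 2,
                                seed = seed)
  models <- read_gene_models_gtf(p("genes.gtf"), reg)
  ex1 <- models$parts[models$parts$gene_id == genes$gene_id[1] &
                        models$parts$part_kind != "intron", ]
  ex1 <- merge_intervals(ex1$start, ex1$end)
  simulate_alignments(p("rna.bam"), fasta, reg, n_reads = 1500,
                      read_length = 60, profile = "exons", exons = ex1,
                      sample = "rna", seed = seed + 3)

  peaks <- simulate_replicate_peaks(p("peaks"), region(chrom, 0, glen),
                                    n_replicates = 3, n_shared = 3,
                                    n_unique = 2, seed = seed)
  simulate_cytoband(p("cytoband.txt"), chrom = chrom, length = glen)
  simulate_contact_matrix(p("contacts.tsv"), reg, binsize = 500,
                          seed = seed)
  pept <- simulate_peptides(p("protein.fa"), p("peptides.tsv"),
                            seed = seed)

  links <- data.frame(start1 = c(12000, 14000), end1 = c(12600, 14400),
                      start2 = c(16500, 18000), end2 = c(17100, 18500))
  utils::write.table(links, p("links.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  feats <- data.frame(start = c(13000, 17500), end = c(13400, 17900),
                      label = c("motif", "repeat"),
                      shape = c("box", "domain"))
  utils::write.table(feats, p("features.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  genome_cfg <- list(
    region = format_region(reg, big_mark = ""),
    tracks = list(
      list(path = "chip.bam", format = "bam", sample = "chip",
           group = "treatment", normalization = "CPM", binsize = 50),
      list(path = "input.bam", format = "bam", sample = "input",
           group = "control", normalization = "CPM", binsize = 50)),
    style = "facet",
    layers = list(
      list(kind = "gc", fasta = "reference.fa", binsize = 100),
      list(kind = "base", bam = "wgs.bam", fasta = "reference.fa",
           region = sprintf("%s:%d-%d", chrom, snv_pos - 9,
                            snv_pos + 10)),
      list(kind = "cnv", bam = "wgs.bam", binsize = 200, ploidy = 2),
      list(kind = "gene", gtf = "genes.gtf"),
      list(kind = "transcript", gtf = "genes.gtf",
           gene_id = genes$gene_id[1]),
      list(kind = "peak", peaks = "peaks/replicate1.narrowPeak"),
      list(kind = "ideogram", cytoband = "cytoband.txt"),
      list(kind = "tad", matrix = "contacts.tsv", binsize = 500),
      list(kind = "link", anchors = "links.tsv"),
      list(kind = "feature", features = "features.tsv")),
    output = list(path = "genome.svg", width = 9))
  yaml::write_yaml(genome_cfg, p("genome.yaml"))

  protein_cfg <- list(
    protein_fasta = "protein.fa",
    peptides = "peptides.tsv",
    layers = list(
      list(kind = "feature",
           features = list(list(start = 10, end = 40, label = "domainA",
                                shape = "domain")))),
    output = list(path = "protein.svg", width = 7))
  yaml::write_yaml(protein_cfg, p("protein.yaml"))

  manifest <- list(
    seed = seed, chrom = chrom, genome_length = glen,
    region = format_region(reg, big_mark = ""),
    snv = list(position = snv_pos, ref = "T", alt = "A", vaf = 1.0),
    chip_peaks = chip_peaks,
    genes = genes,
    consensus_truth = peaks$truth,
    peptides = pept$peptides,
    protein_length = nchar(pept$protein))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(manifest)
}
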