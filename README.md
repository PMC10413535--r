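# covviz

Genome and protein coverage visualization for multi-sample, multi-omics
sequencing experiments, with the preprocessing that coverage figures
usually require built in.

Inspecting read coverage over a locus is the everyday sanity check of NGS
analysis: CNV work needs bin counts next to GC content and the chromosome
ideogram; variant inspection needs per-base pileups, allele frequencies
and amino-acid frames; ChIP-seq needs ChIP-vs-input tracks with called
peaks and nearby gene models; RNA-seq needs exon-resolved coverage against
transcript structure; proteomics needs per-residue peptide coverage of a
protein. `covviz` addresses all of these with one composable grammar: a
coverage panel plus annotation layers stacked with `+`, rendered through
ggplot2/patchwork to PDF/SVG/PNG.

## What it computes

* **Coverage input** from indexed BAM (per-base pileup depth with
  conventional read filtering; spliced `N` gaps uncovered, deletions
  covered), BigWig, BedGraph and pre-binned TSV — always fetching only the
  displayed region, never whole files.
* **Bin normalization**, the deeptools family re-implemented over bin read
  counts `r_i` (5'-end assignment) or per-base depth `d_i`:
  * CPM: `r_i / (N / 10^6)` for `N` total mapped reads
  * RPKM: `r_i / ((w_i/1000) · (N/10^6))` for bin width `w_i`
  * BPM: `r_i / (Σ_j r_j / 10^6)` (values sum to 10^6)
  * RPGC: `d_i / (N·L̄ / G)` — 1× genome coverage scaling with mean read
    length `L̄` and effective genome size `G`
* **Consensus peaks** from replicate peak sets: per peak, the best
  overlapper from each other replicate is collected, the p-values are
  combined by Fisher's method (`X² = −2Σln p ~ χ²_{2k}`), and peaks pass
  with combined `p ≤ γ` and support in at least `min_support` replicates;
  surviving overlapping peaks merge into union intervals.
* **Annotations**: per-bin GC content, per-position base frequencies with
  threshold-based SNV highlighting (three styles), amino-acid frames at
  offsets 0/1/2, gene/transcript glyphs packed into non-overlapping rows
  by greedy first-fit, cytoband ideograms, rotated contact-map triangles,
  arc links, feature boxes, and exact-substring protein peptide coverage.
* **Synthetic data generators** for every input format (reference FASTA
  with GC control, BAMs with planted SNVs / peak enrichment / spliced
  reads, GTFs, replicate narrowPeak sets, peptide tables), all
  byte-deterministic under a seed.

## Worked example

Simulate a 50 kb genome with a planted 100%-VAF T→A variant, load a
region, call the variant and compose a figure:

```r
library(covviz)

fa  <- "ref.fa"; bam <- "sample.bam"
simulate_reference(fa, length = 50000, gc = 0.45, seed = 11)
simulate_alignments(bam, fa, region("chrSim", 0, 50000), n_reads = 10000,
                    read_length = 100,
                    snv = list(position = 14999, alt = "A", vaf = 1),
                    seed = 11)

reg <- parse_region("chrSim:10,001-20,000")
tr  <- read_coverage_bam(bam, reg)
tr
#> <signal_track> sample (group sample) over chrSim:10,001-20,000
#>   values: mean 19.58, max 36

counts <- read_base_counts_bam(bam, region("chrSim", 14989, 15010), fa)
call_snvs(counts)
#>   position ref alt alt_freq depth
#> 1    14999   T   A        1    24

fig <- coverage_figure(tr) +
  layer_gc(read_reference_sequence(fa, reg), binsize = 100) +
  layer_base(counts)
fig
#> <cov_figure> genomic space, region chrSim:10,001-20,000
#>   panels: coverage + gc + base
save_figure(fig, "locus.svg")
```

The mean depth of ~19.6× is the simulated 10,000 × 100 bp over 50 kb
(20×); the variant call reproduces the planted event: at 1-based position
15,000 every one of the 24 overlapping reads carries A over a T
reference, so the alternate allele frequency is 1.0 (100% VAF), and the
base panel hatches that locus with the default "twill" mark, with
amino-acid frames for offsets 0/1/2 drawn underneath.

A declarative YAML config drives the same grammar from the shell:

```sh
Rscript inst/cli/covviz demo --outdir demo --seed 1
Rscript inst/cli/covviz plot --config demo/genome.yaml
Rscript inst/cli/covviz normalize --bam demo/wgs.bam --region chrSim:1-50000 \
    --method CPM --binsize 50 --out wgs.cpm.bedgraph
Rscript inst/cli/covviz consensus --peaks demo/peaks/replicate1.narrowPeak \
    --peaks demo/peaks/replicate2.narrowPeak --peaks demo/peaks/replicate3.narrowPeak \
    --gamma 1e-4 --min-support 2 --out consensus.bed
```

## Package layout

* `R/` — regions/tracks, format readers and writers, normalization,
  consensus, annotations, the layer grammar and renderers, simulators,
  CLI.
* `vignettes/coverage-grammar.Rmd` — the methods notes: model,
  parameters, defaults and their rationale, limitations.
* `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles.
* `inst/cli/covviz` — the Rscript front end (`plot`, `normalize`,
  `consensus`, `demo`).
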