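---
title: "Methods: the covviz coverage grammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the covviz coverage grammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how `covviz` computes what it draws: the coverage
model, the preprocessing statistics, the annotation procedures, the
defaults and the reasoning behind them, and what the synthetic-data
generators do and do not emulate.

## Coordinates

All internal coordinates are 0-based half-open (the BED convention), so
interval arithmetic needs no off-by-one cases: width is `end − start`,
intervals overlap iff `a.start < b.end` and `b.start < a.end`, and
abutting intervals do not overlap. Everything user-facing — region
strings accepted by `parse_region()`, axis tick labels, printed region
summaries — is 1-based inclusive, the convention of UCSC and IGV.
Chromosome names are matched exactly; we deliberately do not strip or add
`"chr"` prefixes, because silent renaming is a classic source of
wrong-region figures. Mismatched naming between files is the user's to
resolve (e.g. by regenerating inputs with consistent headers).

## Coverage from alignments

Per-base depth at a position is the number of retained reads whose
aligned reference span covers it. Retained means: mapped, primary,
passing vendor QC, not a duplicate, and at or above `min_mapq` (default
0, i.e. no MAPQ filtering — multi-mapper handling is left to the caller
because the right cutoff is protocol-specific). Within a read, `M`, `=`,
`X` and `D` CIGAR operations cover the reference; `N` skips (spliced
introns) do not. This is what makes RNA-seq coverage exon-resolved: a
spliced read contributes depth to its exonic blocks only. Deletions count
as covered because the read does span those bases on the reference, and
excluding them would punch single-base holes into otherwise uniform
coverage.

Every reader — BAM, BigWig, BedGraph, and the gene-model GTF reader —
honors a region-subset contract: loading region *R* directly is exactly
equal to loading any superset and slicing to *R*. For BAM and BigWig this
is index-backed random access; for text BedGraph the file is scanned but
only the requested interval is materialized. The property is tested on
randomized sub-regions against all three signal readers.

## Bin normalization

Coverage tracks from libraries of different depth are not comparable raw;
the package re-implements the four standard per-bin normalizations. For
CPM/RPKM/BPM a read is counted in the bin containing its 5'-most
reference position (leftmost aligned base for forward reads, rightmost
for reverse reads) with no fractional assignment — an unambiguous rule
that makes every value checkable by hand. RPGC instead rescales mean
per-base depth so that the genome-wide average becomes 1×:
`scale = total_reads × mean_read_length / effective_genome_size`.
Consequences worth knowing:

* BPM always sums to 10^6 over the binned dataset and is invariant to
  global scaling of counts; CPM/RPKM/RPGC are linear in the counts.
* RPKM divides by the *realized* bin width, so a short terminal bin is
  normalized by its own length, not the nominal bin size.
* Effective genome sizes for hg19/hg38/mm10 ship as constants
  (`effective_genome_sizes`, the commonly used mappable-genome values);
  any number can be passed instead. Default bin size is 50 bp, a common
  browser-track resolution.

`normalize_many()` processes several BAMs independently and serially;
outputs are identical regardless of execution order, and a failing input
yields an error record rather than aborting the batch.

## Consensus peaks from replicates

Replicate peak sets are combined by evidence, not by voting alone. For
each peak we collect the single best (smallest-p) overlapping peak from
every other replicate (overlap means at least 1 bp); `support` is one
plus the number of contributing replicates. The collected p-values,
including the peak's own, are combined by Fisher's method:
`X² = −2 Σ ln p` referred to a chi-square distribution with `2k` degrees
of freedom. A peak survives if `support ≥ min_support` and the combined
p-value is at most `gamma`; surviving peaks that overlap across
replicates merge into one consensus interval spanning their union and
carrying the group's smallest combined p (ties broken by leftmost start,
for determinism). Replicates without p-values (plain BED) participate
with p = 1, the weakest admissible evidence.

This is a deliberate simplification of the full MSPC-style machinery: we
kept the combined-evidence core (Fisher across replicates plus a support
requirement) and dropped the weak/stringent dual-threshold classification
and the FDR stage. The two exposed knobs, `gamma` (stringency on the
combined p) and `min_support`, are easy to reason about and the
procedure is monotone in `gamma`: relaxing it never removes peaks.
Defaults are `gamma = 1e-8`, `min_support = 2`.

## Annotations

**GC content** per bin is `(G+C)/(A+C+G+T)` with `N` ignored; an all-`N`
bin is undefined (`NA`) and excluded from the mean line. The reference
line is the whole-region GC by default; a numeric constant (e.g. a
genome-wide average from elsewhere) can be drawn instead — we expose
mean-or-constant and leave the meaning of the constant to the user.

**SNV calling** is a display-oriented frequency rule, not a genotyper: a
position is flagged when depth ≥ `min_depth` (default 10) and the most
frequent non-reference base reaches `min_alt_freq` (default 0.2). Ties
between alternate bases break in A,C,G,T order. The defaults flag
heterozygous-like events at typical inspection depths while ignoring
sequencing-error noise; both are settable. Raising `min_alt_freq` can
only remove calls (tested as a property). Flagged loci render in one of
three highlight styles — `twill` (diagonal hatching over the locus, the
default), `strip` (translucent background), `letter` (colored alternate
base letter only); the trio is our reconstruction of the customary
highlight variants, selectable per layer.

**Amino-acid frames** translate the displayed reference sequence at
forward offsets 0/1/2 with the standard genetic code; codons containing
`N` render as `X` and trailing partial codons are dropped. Each residue
carries its 3-bp genomic span so the letters align under the bases.
Reverse-strand frames are intentionally not drawn by default — six rows
overwhelm the panel; the forward three match the usual browser display.

**Row packing** for gene/transcript/peptide glyphs is greedy first-fit:
intervals sorted by start (ties: longer first), each placed in the
lowest row keeping `min_gap` clearance. For interval graphs this greedy
order is optimal — rows used equal the maximum overlap depth — which the
tests verify against a brute-force clique count. The default gap is 1% of
the displayed width: packing is a display-space problem (labels collide
in pixels, not base pairs).

**Gene glyphs** draw parts at heights exon 1.0 > UTR 0.6 > intron 0.15 of
a lane, a rightward arrow for `+` genes (dark green) and leftward for `−`
(dark blue). When the GTF has explicit UTR features they are used;
otherwise UTR is derived as exon minus CDS; with neither, everything is
exon and gaps between merged exons become introns. This degrades
gracefully across GTF dialects.

**Contact maps** are read as dense square TSVs (a deliberately simple
interchange format rather than a binary Hi-C container), symmetrized as
`(M + Mᵀ)/2` (with a warning beyond 1e-6 relative asymmetry), and drawn
as the conventional 45°-rotated upper triangle: cell `(i, j)` becomes a
diamond at `x = start + ((i+j)/2 + 0.5)·binsize`, `y = j − i`, so
diagonal cells sit exactly above their genomic bins. Color is `log1p` of
counts.

**Protein coverage** counts every exact occurrence of every peptide
(overlapping occurrences included, one increment each). Leucine and
isoleucine are not equated — they are distinct residues even if
isobaric; mass-based ambiguity resolution is out of scope. Peptides with
characters outside the 20-letter alphabet are skipped and recorded.

## The figure grammar

A figure is one coverage panel (or one protein panel) plus annotation
panels, composed with `+`. Composition is non-mutating and
order-preserving: panel order is addition order, a second
coverage/protein layer is an error, and protein-space layers cannot mix
with genomic ones (feature layers work in both spaces). Default relative
heights give the coverage panel dominance (coverage 4; base 1.5 + 0.5 per
amino-acid row; tad 3; gene/transcript 0.4 per packed row; the small
annotations 0.5–1), all overridable per layer.

Coverage panels offer `facet` (one sub-panel per sample, colored by
group) and `joint` (overlaid, translucent) styles; facet panels can share
one y-scale or use free scales (`y_scale = "shared"`/`"free"`) — our
reading of the customary third display variant. The ideogram panel maps
whole-chromosome band coordinates linearly onto the figure's x-span so
that every panel, ideogram included, shares one x-domain (this keeps the
stacked axes aligned and is what the layout tests assert); the displayed
region is marked by a red rectangle and `acen` centromere bands are
green.

Rendering goes through ggplot2 and patchwork; `realized_layout()`
exposes the built layout (panel kinds, height weights, x-ranges, facet
sub-panel counts) for structural testing. SVG output through the cairo
device is byte-deterministic for identical inputs, which the tests
exploit (`save twice, compare bytes`). The YAML config consumed by the
CLI is the declarative twin of `+`: its ordered `layers` list maps
one-to-one onto panels, so a config with a second coverage block is a
schema error, mirroring the composition rule.

## Synthetic data: what it emulates, what it does not

The generators produce every input the package reads, deterministically
under a seed, with per-generator random streams so changing one plan
never perturbs another's output. They emulate the *structural* features
the visualizations and statistics depend on: controllable GC by window
(±0.05 realized at 10 kb windows, binomial concentration), planted SNVs
reproduced at a target VAF, peak enrichment against a uniform background,
spliced reads confined to exons, replicate peak sets with a planned
consensus subset (shared p-values log-uniform in [1e-10, 1e-6], noise in
[0.01, 0.5], placed in disjoint slots so noise can never gain cross-replicate
support), and peptide tables that are exact substrings plus guaranteed
non-matching decoys.

They do not emulate sequencing realism: no indels or base-quality decay,
single-end reads only, no fragment-length model, no mapping ambiguity.
Green tests therefore certify the *computations* — pileup arithmetic,
normalization formulas, combination statistics, layout invariants — not
robustness to real-world artifacts like mapping bias or duplicated
regions.

Problem sizes in the test suite and acceptance script (20–50 kb genomes,
hundreds to thousands of reads, 3 replicates × 5 peaks, 500-case layout
sweeps, 1000-sequence translation sweeps) were chosen as the smallest
sizes at which each property is non-trivially exercised — e.g. enough
reads that spliced, deleted and plain CIGARs all occur, and enough depth
that default SNV thresholds are meaningful.

## Numerical and degenerate-input choices

* BedGraph values are written with `%.17g`, so write/read round-trips
  reproduce doubles exactly.
* Zero-depth pileup positions yield all-zero base frequencies, not NaN.
* An empty bin set or all-zero BPM input returns zeros rather than
  dividing by zero.
* `fisher_combine` rejects p ≤ 0 (log-domain) and accepts p = 1; a single
  p-value is returned unchanged (k = 1 identity).
* Contact matrices are always symmetrized; the warning threshold (1e-6
  relative) separates numerical noise from genuinely asymmetric input.
* Terminal short bins aggregate only their own positions.
* Consensus ties (identical combined p) and SNV alternate-base ties have
  fixed, documented break orders so outputs are reproducible.

## Known limitations

* No CRAM, tabix-indexed BedGraph, remote URLs, or binary Hi-C (.hic /
  .cool) containers; contact maps must be exported to dense TSV.
* Native `.xlsx` peptide workbooks are not parsed; export TSV/CSV from
  the analyzer (only the sequence column is required anyway).
* Copy-number panels display provided segments; no segmentation or
  estimation is performed.
* The consensus procedure is the simplified combined-evidence rule
  described above, not the full MSPC state machine.
* Whole-genome multi-chromosome layouts and assembly liftover are out of
  scope; one figure shows one region of one chromosome.
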