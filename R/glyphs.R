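# Display-ready assemblies: gene/transcript glyph layout, CNV tracks,
# protein peptide coverage.

# Draw heights of gene parts as fractions of a lane (exon > UTR > intron).
PART_HEIGHTS <- c(exon = 1.0, UTR = 0.6, intron = 0.15)

glyph_rows <- function(ids, labels, strand, color_key, starts, ends,
                       parts_by_id, region, min_gap = NULL) {
  # clip extents to the displayed region for packing (display-space rule)
  s <- pmax(starts, region$start)
  e <- pmin(ends, region$end)
  keep <- which(s < e)
  if (is.null(min_gap)) min_gap <- 0.01 * region_length(region)
  rows <- assign_rows(s[keep], e[keep], min_gap = min_gap)
  glyphs <- list()
  for (j in seq_along(keep)) {
    i <- keep[j]
    parts <- parts_by_id[[ids[i]]]
    parts$height <- unname(PART_HEIGHTS[parts$part_kind])
    glyphs[[j]] <- list(feature_id = ids[i], label = labels[i],
                        row = rows[j], strand = strand[i],
                        color_key = color_key[i], start = s[keep][j],
                        end = e[keep][j], parts = parts)
  }
  glyphs
}

#' Gene glyphs with row layout for a displayed region
#'
#' One glyph per gene overlapping the region: parts drawn at heights exon >
#' UTR > intron (1.0 / 0.6 / 0.15 of the lane), strand arrows pointing
#' right for `+` and left for `-`, and color keyed by strand (`"plus"` /
#' `"minus"`) unless the model carries a user group label. Rows come from
#' [assign_rows()] with a default gap of 1% of the region width so labels
#' do not collide.
#'
#' @param models A `gene_model_set` from [read_gene_models_gtf()].
#' @param region The displayed [region()].
#' @param min_gap Row-packing gap in bp (default 1% of region width).
#' @return List of glyphs (feature id, label, row, strand, color key,
#'   clipped extent, parts with draw heights).
#' @export
build_gene_glyphs <- function(models, region, min_gap = NULL) {
  stopifnot(inherits(models, "gene_model_set"))
  g <- models$genes
  if (nrow(g) == 0) return(list())
  parts_by_id <- split(models$parts[, c("part_kind", "start", "end")],
                       models$parts$gene_id)
  color_key <- ifelse(!is.na(g$group), g$group,
                      ifelse(g$strand == "+", "plus", "minus"))
  glyph_rows(g$gene_id, g$gene_name, g$strand, color_key, g$start, g$end,
             parts_by_id, region, min_gap)
}

#' Transcript glyphs for one gene
#'
#' Like [build_gene_glyphs()] but one glyph per transcript of `gene_id`,
#' labeled by transcript id.
#'
#' @param models A `gene_model_set`.
#' @param gene_id Gene whose transcripts to lay out.
#' @param region The displayed [region()].
#' @param min_gap Row-packing gap in bp.
#' @return List of glyphs.
#' @export
build_transcript_glyphs <- function(models, gene_id, region,
                                    min_gap = NULL) {
  stopifnot(inherits(models, "gene_model_set"))
  tx <- models$transcripts[models$transcripts$gene_id == gene_id, ,
                           drop = FALSE]
  if (nrow(tx) == 0) {
    stop("not found: gene_id '", gene_id, "' has no transcripts in the ",
         "model set", call. = FALSE)
  }
  parts_by_id <- split(models$tx_parts[, c("part_kind", "start", "end")],
                       models$tx_parts$transcript_id)
  color_key <- ifelse(tx$strand == "+", "plus", "minus")
  glyph_rows(tx$transcript_id, tx$transcript_id, tx$strand, color_key,
             tx$start, tx$end, parts_by_id, region, min_gap)
}

#' Assemble a copy-number display track
#'
#' Pure assembly, no estimation: normalized bin counts become dots, the
#' provided segments a step line at their copy number, and the ploidy a
#' horizontal reference line.
#'
#' @param bins A [binned_signal()] of normalized counts.
#' @param segments Data frame with `chrom`, `start`, `end`, `copy_number`
#'   (may be empty); segments must lie within the bins' region and must not
#'   overlap.
#' @param ploidy Integer >= 1.
#' @return An object of class `cnv_track`.
#' @export
build_cnv_track <- function(bins, segments = NULL, ploidy = 2) {
  stopifnot(is_binned_signal(bins))
  if (ploidy < 1) stop("validation error: ploidy must be >= 1",
                       call. = FALSE)
  if (is.null(segments) || nrow(segments) == 0) {
    segments <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), copy_number = numeric())
  } else {
    segments <- segments[order(segments$start), , drop = FALSE]
    within <- segments$chrom == bins$region$chrom &
      segments$start >= bins$region$start & segments$end <= bins$region$end
    if (!all(within)) {
      stop("validation error: segment outside the binned region",
           call. = FALSE)
    }
    if (nrow(segments) > 1 &&
        any(segments$start[-1] < segments$end[-nrow(segments)])) {
      stop("validation error: overlapping copy-number segments",
           call. = FALSE)
    }
  }
  structure(list(bins = bins, segments = segments,
                 ploidy = as.integer(ploidy)), class = "cnv_track")
}

#' Protein coverage from identified peptides
#'
#' Every exact occurrence of every peptide in the protein contributes +1
#' depth over its residues; a peptide matching at several (possibly
#' overlapping) positions contributes at each. Leucine and isoleucine are
#' not equated. Peptides with characters outside the 20-letter amino-acid
#' alphabet are skipped and recorded.
#'
#' @param protein_sequence Amino-acid string.
#' @param peptides A [read_peptides()] table, or a character vector of
#'   peptide sequences.
#' @return An object of class `protein_coverage`: `length`, `depth`
#'   (per-residue), `matches` (peptide, start, end; 1-based inclusive
#'   residues), `skipped` (invalid peptides).
#' @export
protein_coverage <- function(protein_sequence, peptides) {
  if (!is.character(protein_sequence) || length(protein_sequence) != 1L ||
      !nzchar(protein_sequence)) {
    stop("protein_coverage: non-empty protein sequence required",
         call. = FALSE)
  }
  prot <- toupper(protein_sequence)
  if (inherits(peptides, "peptide_table") || is.data.frame(peptides)) {
    peptides <- peptides$peptide
  }
  peptides <- toupper(as.character(peptides))
  L <- nchar(prot)
  depth <- integer(L)
  matches <- NULL
  skipped <- character()
  aa_ok <- paste0("^[", paste(AA_LETTERS, collapse = ""), "]+$")
  subject <- Biostrings::AAString(prot)
  for (pep in peptides) {
    if (!grepl(aa_ok, pep)) {
      warning("skipping peptide with illegal characters: ", pep,
              call. = FALSE)
      skipped <- c(skipped, pep)
      next
    }
    if (nchar(pep) > L) next
    hits <- Biostrings::matchPattern(pep, subject)
    for (h in seq_along(hits)) {
      s <- Biostrings::start(hits)[h]
      e <- Biostrings::end(hits)[h]
      depth[s:e] <- depth[s:e] + 1L
      matches <- rbind(matches, data.frame(peptide = pep, start = s,
                                           end = e))
    }
  }
  if (is.null(matches)) {
    matches <- data.frame(peptide = character(), start = integer(),
                          end = integer())
  }
  structure(list(protein_id = "protein", length = L, depth = depth,
                 matches = matches, skipped = skipped),
            class = "protein_coverage")
}

#' @export
print.protein_coverage <- function(x, ...) {
  cat("<protein_coverage> ", x$length, " residues, ",
      nrow(x$matches), " peptide match(es), covered fraction ",
      signif(mean(x$depth > 0), 4), "\n", sep = "")
  invisible(x)
}
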