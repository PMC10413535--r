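# Gene model construction from GTF. Coordinates are converted from GTF's
# 1-based inclusive convention to the internal 0-based half-open one.

# Reduce a set of 0-based half-open intervals to a sorted disjoint union.
merge_intervals <- function(start, end) {
  if (length(start) == 0) return(data.frame(start = numeric(),
                                            end = numeric()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# Set difference a \ b on 0-based half-open interval sets.
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0) return(a)
  b <- merge_intervals(b$start, b$end)
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    cur <- s
    if (nrow(b) > 0) {
      for (j in seq_len(nrow(b))) {
        bs <- b$start[j]; be <- b$end[j]
        if (be <= cur || bs >= e) next
        if (bs > cur) { out_s <- c(out_s, cur); out_e <- c(out_e, bs) }
        cur <- max(cur, be)
        if (cur >= e) break
      }
    }
    if (cur < e) { out_s <- c(out_s, cur); out_e <- c(out_e, e) }
  }
  data.frame(start = out_s, end = out_e)
}

# exon/UTR/CDS feature rows -> parts (exon/UTR/intron) for one model.
derive_parts <- function(ex, utr, cds) {
  merged <- merge_intervals(ex$start, ex$end)
  if (nrow(merged) == 0) return(data.frame(part_kind = character(),
                                           start = numeric(),
                                           end = numeric()))
  if (nrow(utr) > 0) {
    utr_m <- merge_intervals(utr$start, utr$end)
    exon_parts <- subtract_intervals(merged, utr_m)
    utr_parts <- utr_m
  } else if (nrow(cds) > 0) {
    cds_m <- merge_intervals(cds$start, cds$end)
    utr_parts <- subtract_intervals(merged, cds_m)
    exon_parts <- subtract_intervals(merged, utr_parts)
  } else {
    exon_parts <- merged
    utr_parts <- data.frame(start = numeric(), end = numeric())
  }
  # introns: gaps between merged exons
  intr <- if (nrow(merged) > 1) {
    data.frame(start = merged$end[-nrow(merged)], end = merged$start[-1])
  } else data.frame(start = numeric(), end = numeric())
  parts <- rbind(
    if (nrow(exon_parts)) cbind(part_kind = "exon", exon_parts),
    if (nrow(utr_parts)) cbind(part_kind = "UTR", utr_parts),
    if (nrow(intr)) cbind(part_kind = "intron", intr))
  parts[order(parts$start), , drop = FALSE]
}

#' Read gene models overlapping a region from a GTF file
#'
#' Exon features define the models; introns are inferred as gaps between a
#' model's merged exons. UTR parts come from UTR features when the file has
#' them, otherwise from exon-minus-CDS; files with neither draw everything
#' as exon. Genes that merely touch the region are included whole (clipping
#' happens at draw time). Both gene-level and per-transcript part sets are
#' built.
#'
#' @param path GTF path with `gene_id`/`transcript_id` attributes.
#' @param region A [region()].
#' @return An object of class `gene_model_set` with data frames `genes`,
#'   `parts` (gene-level), `transcripts` and `tx_parts`.
#' @export
read_gene_models_gtf <- function(path, region) {
  if (!file.exists(path)) {
    stop("format error: GTF file '", path, "' not found", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id)) {
    stop("format error: GTF has no gene_id attribute", call. = FALSE)
  }
  type <- tolower(as.character(md$type))
  is_utr <- type %in% c("utr", "five_prime_utr", "three_prime_utr",
                        "5utr", "3utr")
  feat <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,   # -> 0-based half-open
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = ifelse(is_utr, "utr", type),
    gene_id = as.character(md$gene_id),
    gene_name = if (!is.null(md$gene_name)) as.character(md$gene_name)
                else as.character(md$gene_id),
    transcript_id = if (!is.null(md$transcript_id))
                      as.character(md$transcript_id) else NA_character_,
    group = if (!is.null(md$gene_biotype)) as.character(md$gene_biotype)
            else NA_character_)
  feat <- feat[feat$type %in% c("exon", "cds", "utr"), , drop = FALSE]
  feat$gene_name[is.na(feat$gene_name)] <- feat$gene_id[is.na(feat$gene_name)]

  # genes overlapping the region (by exon extent), kept whole
  ex <- feat[feat$type == "exon", , drop = FALSE]
  keep_ids <- unique(ex$gene_id[ex$chrom == region$chrom &
                                ex$start < region$end &
                                ex$end > region$start])
  feat <- feat[feat$gene_id %in% keep_ids, , drop = FALSE]

  genes <- NULL; parts <- NULL; transcripts <- NULL; tx_parts <- NULL
  for (gid in keep_ids) {
    g <- feat[feat$gene_id == gid, , drop = FALSE]
    strand <- g$strand[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    gp <- derive_parts(g[g$type == "exon", c("start", "end")],
                       g[g$type == "utr", c("start", "end")],
                       g[g$type == "cds", c("start", "end")])
    genes <- rbind(genes, data.frame(
      gene_id = gid, gene_name = g$gene_name[1], strand = strand,
      group = g$group[1], start = min(gp$start), end = max(gp$end)))
    parts <- rbind(parts, cbind(gene_id = gid, gp))
    for (tid in unique(stats::na.omit(g$transcript_id))) {
      t <- g[!is.na(g$transcript_id) & g$transcript_id == tid, , drop = FALSE]
      tp <- derive_parts(t[t$type == "exon", c("start", "end")],
                         t[t$type == "utr", c("start", "end")],
                         t[t$type == "cds", c("start", "end")])
      if (nrow(tp) == 0) next
      transcripts <- rbind(transcripts, data.frame(
        transcript_id = tid, gene_id = gid, strand = strand,
        start = min(tp$start), end = max(tp$end)))
      tx_parts <- rbind(tx_parts, cbind(transcript_id = tid, tp))
    }
  }
  empty <- function(...) data.frame(...)
  structure(list(
    genes = if (is.null(genes))
      empty(gene_id = character(), gene_name = character(),
            strand = character(), group = character(), start = numeric(),
            end = numeric()) else genes,
    parts = if (is.null(parts))
      empty(gene_id = character(), part_kind = character(),
            start = numeric(), end = numeric()) else parts,
    transcripts = if (is.null(transcripts))
      empty(transcript_id = character(), gene_id = character(),
            strand = character(), start = numeric(), end = numeric())
      else transcripts,
    tx_parts = if (is.null(tx_parts))
      empty(transcript_id = character(), part_kind = character(),
            start = numeric(), end = numeric()) else tx_parts),
    class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("<gene_model_set> ", nrow(x$genes), " gene(s), ",
      nrow(x$transcripts), " transcript(s)\n", sep = "")
  invisible(x)
}
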