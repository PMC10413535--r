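# Peak, cytoband, contact-matrix and peptide-table readers.

#' Construct a peak set
#'
#' @param chrom,start,end Peak coordinates (0-based half-open).
#' @param name Peak names.
#' @param score Numeric scores.
#' @param p_value Optional p-values in (0, 1]; `NA` where absent.
#' @param summit Optional summit offsets from `start`; `NA` where absent.
#' @param source Label describing where the peaks came from.
#' @return An object of class `peak_set`: a data frame with one row per peak.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0,
                     p_value = NA_real_, summit = NA_real_,
                     source = "peaks") {
  n <- length(start)
  if (is.null(name)) {
    name <- if (n == 0) character() else paste0("peak_", seq_len(n))
  }
  pv <- rep_len(as.numeric(p_value), n)
  if (any(!is.na(pv) & (pv <= 0 | pv > 1))) {
    stop("peak_set: p-values must lie in (0, 1]", call. = FALSE)
  }
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = as.character(name),
                   score = rep_len(as.numeric(score), n), p_value = pv,
                   summit = rep_len(as.numeric(summit), n))
  if (any(df$start >= df$end)) stop("peak_set: empty peak interval",
                                    call. = FALSE)
  structure(df, class = c("peak_set", "data.frame"), source = source)
}

#' Read peaks from BED or ENCODE narrowPeak
#'
#' Files with 10 or more columns are treated as narrowPeak: column 8 is
#' -log10(p) (`-1` is the ENCODE missing-value sentinel), column 10 the
#' summit offset. Plain BED yields peaks without p-values.
#'
#' @param path BED3+/narrowPeak path.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) {
    stop("format error: peak file '", path, "' not found", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    return(peak_set(character(), numeric(), numeric(),
                    source = basename(path)))
  }
  fields <- strsplit(lines, "[ \t]+")
  nc <- min(vapply(fields, length, 1L))
  col <- function(j) vapply(fields, `[`, "", j)
  chrom <- col(1); start <- as.numeric(col(2)); end <- as.numeric(col(3))
  name <- if (nc >= 4) col(4) else paste0("peak_", seq_along(chrom))
  score <- if (nc >= 5) as.numeric(col(5)) else 0
  if (nc >= 10) {
    mlog10p <- as.numeric(col(8))
    p <- ifelse(mlog10p < 0, NA_real_, 10^(-mlog10p))
    summit <- as.numeric(col(10))
    summit[summit < 0] <- NA_real_
    peak_set(chrom, start, end, name, score, p, summit,
             source = basename(path))
  } else {
    peak_set(chrom, start, end, name, score, source = basename(path))
  }
}

#' Read a UCSC cytoband file
#'
#' Five tab-separated columns: chrom, start, end, band name, Giemsa stain
#' code. Bands are sorted per chromosome and must not overlap. Stain
#' `"acen"` marks centromere bands.
#'
#' @param path cytoBand.txt path (optionally without header).
#' @return An object of class `cytoband_set` (data frame of bands) with a
#'   `chrom_lengths` attribute.
#' @export
read_cytoband <- function(path) {
  if (!file.exists(path)) {
    stop("format error: cytoband file '", path, "' not found", call. = FALSE)
  }
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "band",
                                        "stain"))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("format error: overlapping cytobands on ", ch, call. = FALSE)
    }
  }
  lens <- tapply(df$end, df$chrom, max)
  structure(df, class = c("cytoband_set", "data.frame"),
            chrom_lengths = lens)
}

#' Read a dense chromatin contact matrix
#'
#' A square whitespace-separated numeric matrix over the region's bins.
#' Asymmetry beyond a relative tolerance of 1e-6 triggers a warning; the
#' matrix is always symmetrized as (M + t(M)) / 2.
#'
#' @param path TSV path of the dense matrix.
#' @param region A [region()].
#' @param binsize Bin width in bp; the matrix dimension must equal
#'   `ceiling(region_length(region) / binsize)`.
#' @return An object of class `contact_matrix`.
#' @export
read_contact_matrix <- function(path, region, binsize) {
  if (!file.exists(path)) {
    stop("format error: matrix file '", path, "' not found", call. = FALSE)
  }
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) {
    stop("shape error: contact matrix must be square, got ", nrow(m), " x ",
         ncol(m), call. = FALSE)
  }
  n_expected <- ceiling(region_length(region) / binsize)
  if (nrow(m) != n_expected) {
    stop("shape error: region of ", region_length(region), " bp at binsize ",
         binsize, " requires a ", n_expected, " x ", n_expected, " matrix",
         call. = FALSE)
  }
  if (any(m < 0)) stop("shape error: negative contact counts", call. = FALSE)
  asym <- max(abs(m - t(m)))
  scale <- max(abs(m), 1e-300)
  if (asym / scale > 1e-6) {
    warning("contact matrix asymmetric beyond tolerance; symmetrizing",
            call. = FALSE)
  }
  m <- (m + t(m)) / 2
  structure(list(region = region, binsize = binsize, matrix = m),
            class = "contact_matrix")
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a peptide table
#'
#' Accepts TSV/CSV exports with a peptide-sequence column (default header
#' `"Sequence"`, matched case-insensitively); every other analyzer column is
#' carried along but ignored by the coverage computation. Native `.xlsx`
#' workbooks are not read; export the sheet as TSV/CSV first.
#'
#' @param path TSV or CSV path.
#' @param sequence_col Name of the peptide-sequence column.
#' @return An object of class `peptide_table` (data frame with at least a
#'   `peptide` column, plus `intensity`/`count` when present).
#' @export
read_peptides <- function(path, sequence_col = "Sequence") {
  if (!file.exists(path)) {
    stop("format error: peptide file '", path, "' not found", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    stop("format error: native Excel workbooks are not supported; ",
         "export the sheet as TSV or CSV", call. = FALSE)
  }
  df <- if (ext == "csv") utils::read.csv(path, check.names = FALSE)
        else utils::read.delim(path, check.names = FALSE)
  j <- match(tolower(sequence_col), tolower(names(df)))
  if (is.na(j)) {
    stop("schema error: peptide-sequence column '", sequence_col,
         "' missing from '", path, "'", call. = FALSE)
  }
  pep <- toupper(trimws(as.character(df[[j]])))
  if (any(!nzchar(pep))) {
    stop("schema error: empty peptide sequence in '", path, "'",
         call. = FALSE)
  }
  out <- data.frame(peptide = pep)
  ji <- match(c("intensity", "abundance"), tolower(names(df)))
  ji <- ji[!is.na(ji)]
  if (length(ji) > 0) out$intensity <- as.numeric(df[[ji[1]]])
  jc <- match(c("count", "psms", "spectra"), tolower(names(df)))
  jc <- jc[!is.na(jc)]
  if (length(jc) > 0) out$count <- as.numeric(df[[jc[1]]])
  structure(out, class = c("peptide_table", "data.frame"))
}
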