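#' Read a BED file of peaks or features
#'
#' Accepts BED3 and wider. `track`, `browser` and `#` comment lines are
#' skipped. Coordinates are kept exactly as read (0-based half-open).
#'
#' @param path path to a tab-separated BED file.
#' @return Interval `data.frame` (see [genomic_intervals()]). Column 4 is
#'   used as the interval name when present; otherwise names are
#'   auto-generated as `peak_<line>` from the 1-based line number in the
#'   file. Column 6, when present, is the strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3))
    stop(sprintf("BED parse error at line %d of %s: fewer than 3 columns",
                 idx[which(ncols < 3)[1]], path), call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d of %s: non-integer coordinates",
                 idx[bad[1]], path), call. = FALSE)
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop(sprintf("BED parse error at line %d of %s: start >= end",
                 idx[bad[1]], path), call. = FALSE)
  name <- ifelse(ncols >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                 paste0("peak_", idx))
  strand <- ifelse(ncols >= 6, vapply(fields, function(f) f[min(6, length(f))], ""), ".")
  strand[!strand %in% c("+", "-")] <- "."
  genomic_intervals(chrom, start, end, name = name, strand = strand)
}

#' Read a BED12 gene-model file
#'
#' Each record carries the transcript span, strand, thick (CDS) bounds and
#' the exon block structure. Strand is mandatory (`+` or `-`): template
#' strand assignment is meaningless without it.
#'
#' @param path path to a 12-column tab-separated BED12 file.
#' @return A `data.frame` of gene models with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `thick_start`, `thick_end`,
#'   `block_count`, and list columns `block_sizes`, `block_starts`
#'   (exon lengths and offsets relative to `start`). Records sharing a gene
#'   name are kept as separate rows.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop("BED12 file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_gene_table())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  if (any(lengths(fields) < 12))
    stop(sprintf("BED12 parse error at line %d of %s: need 12 columns",
                 idx[which(lengths(fields) < 12)[1]], path), call. = FALSE)
  parse_csv_ints <- function(s) as.numeric(strsplit(sub(",+$", "", s), ",")[[1]])
  g <- data.frame(
    chrom = vapply(fields, `[[`, "", 1),
    start = as.numeric(vapply(fields, `[[`, "", 2)),
    end = as.numeric(vapply(fields, `[[`, "", 3)),
    name = vapply(fields, `[[`, "", 4),
    score = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5))),
    strand = vapply(fields, `[[`, "", 6),
    thick_start = as.numeric(vapply(fields, `[[`, "", 7)),
    thick_end = as.numeric(vapply(fields, `[[`, "", 8)),
    block_count = as.numeric(vapply(fields, `[[`, "", 10)),
    stringsAsFactors = FALSE)
  g$block_sizes <- lapply(fields, function(f) parse_csv_ints(f[[11]]))
  g$block_starts <- lapply(fields, function(f) parse_csv_ints(f[[12]]))
  for (i in seq_len(nrow(g))) {
    rec <- sprintf("BED12 record '%s' (line %d of %s)", g$name[i], idx[i], path)
    check_gene_model(g[i, ], rec)
  }
  g
}

empty_gene_table <- function() {
  g <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                  name = character(0), score = numeric(0), strand = character(0),
                  thick_start = numeric(0), thick_end = numeric(0),
                  block_count = numeric(0), stringsAsFactors = FALSE)
  g$block_sizes <- list()
  g$block_starts <- list()
  g
}

# Structural invariants of one gene-model row; `rec` labels error messages.
check_gene_model <- function(gene, rec = sprintf("gene '%s'", gene$name[1])) {
  sizes <- gene$block_sizes[[1]]
  starts <- gene$block_starts[[1]]
  if (!gene$strand[1] %in% c("+", "-"))
    stop(rec, ": gene strand must be + or -", call. = FALSE)
  if (is.na(gene$start[1]) || gene$start[1] < 0 || gene$start[1] >= gene$end[1])
    stop(rec, ": invalid span", call. = FALSE)
  if (length(sizes) != gene$block_count[1] || length(starts) != gene$block_count[1])
    stop(rec, ": blockCount disagrees with blockSizes/blockStarts", call. = FALSE)
  if (any(sizes <= 0)) stop(rec, ": non-positive block size", call. = FALSE)
  if (is.unsorted(starts, strictly = TRUE))
    stop(rec, ": blocks not sorted", call. = FALSE)
  if (starts[1] != 0)
    stop(rec, ": first block must start at offset 0", call. = FALSE)
  if (any(starts[-1] < (starts + sizes)[-length(sizes)]))
    stop(rec, ": overlapping blocks", call. = FALSE)
  last_end <- gene$start[1] + starts[length(starts)] + sizes[length(sizes)]
  if (last_end != gene$end[1])
    stop(rec, ": last block must end at chromEnd", call. = FALSE)
  if (gene$thick_start[1] < gene$start[1] || gene$thick_end[1] > gene$end[1] ||
      gene$thick_start[1] > gene$thick_end[1])
    stop(rec, ": thick bounds outside span", call. = FALSE)
  invisible(gene)
}

#' Read a 2-column gene-expression table
#'
#' Values are taken as-is (TPM, FPKM or any other non-negative normalized
#' metric); the annotator never rescales or log-transforms them, so any
#' metric whose threshold classes agree gives identical annotations.
#'
#' @param path path to a tab- or whitespace-separated 2-column file
#'   (gene name, expression value), or `NULL` for "no expression mode".
#'   A header line is detected (and skipped) when its second field is
#'   non-numeric.
#' @return Named numeric vector of expression values. Duplicated gene names
#'   are resolved to their maximum value with a warning. `NULL` path gives
#'   an empty vector.
#' @export
read_expression_table <- function(path = NULL) {
  if (is.null(path)) return(stats::setNames(numeric(0), character(0)))
  if (!file.exists(path)) stop("expression table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) return(stats::setNames(numeric(0), character(0)))
  fields <- strsplit(trimws(lines), "[\t ]+")
  if (any(lengths(fields) < 2))
    stop("expression table parse error: need 2 columns on every line", call. = FALSE)
  v1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  if (is.na(v1[1]) && length(v1) >= 1) {  # header
    fields <- fields[-1]
    v1 <- v1[-1]
  }
  if (any(is.na(v1)))
    stop("expression table parse error: non-numeric value at data line ",
         which(is.na(v1))[1], call. = FALSE)
  if (any(v1 < 0))
    stop("expression table parse error: negative value at data line ",
         which(v1 < 0)[1], call. = FALSE)
  gene <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(gene)) {
    warning("duplicate gene names in expression table; keeping the maximum value")
    v1 <- vapply(split(v1, gene), max, 0)[unique(gene)]
    gene <- unique(gene)
  }
  stats::setNames(as.numeric(v1), gene)
}

#' Read a chromosome-sizes table
#'
#' @param path 2-column tab-separated file: chromosome name, length in bp.
#' @return Named numeric vector of chromosome lengths (all > 0).
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes not found: ", path, call. = FALSE)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  if (any(x$length <= 0)) stop("chrom.sizes: non-positive length", call. = FALSE)
  stats::setNames(x$length, x$chrom)
}

#' Load a gene reference-set folder
#'
#' The folder must contain `genes.bed12` and `chrom.sizes`. Optional
#' per-feature BED files (`5UTR.bed`, `3UTR.bed`, `exon.bed`, `intron.bed`,
#' BED with the gene name in column 4) take precedence over features derived
#' from the BED12 blocks unless `derive = TRUE`.
#'
#' @param dir path to the reference folder.
#' @param derive force derivation of features from the BED12 even when
#'   per-feature BED files are present.
#' @return A list of class `rloop_reference`: `genes` (see [read_bed12()]),
#'   `chrom_sizes` (named numeric), and `features` (`NULL`, or a named list
#'   of interval tables for `utr5`, `utr3`, `exons`, `introns`).
#' @export
load_reference <- function(dir, derive = FALSE) {
  bed12 <- file.path(dir, "genes.bed12")
  sizes <- file.path(dir, "chrom.sizes")
  for (f in c(bed12, sizes))
    if (!file.exists(f)) stop("reference folder is missing ", basename(f), call. = FALSE)
  feature_files <- c(utr5 = "5UTR.bed", utr3 = "3UTR.bed",
                     exons = "exon.bed", introns = "intron.bed")
  features <- NULL
  if (!derive && all(file.exists(file.path(dir, feature_files))))
    features <- lapply(file.path(dir, feature_files), read_bed)
  if (!is.null(features)) names(features) <- names(feature_files)
  structure(list(genes = read_bed12(bed12),
                 chrom_sizes = read_chrom_sizes(sizes),
                 features = features, dir = dir),
            class = "rloop_reference")
}

#' @export
print.rloop_reference <- function(x, ...) {
  cat(sprintf("Gene reference set: %d gene models on %d chromosomes\n",
              nrow(x$genes), length(x$chrom_sizes)))
  cat(sprintf("Features: %s\n",
              if (is.null(x$features)) "derived from BED12 blocks"
              else "loaded from per-feature BED files"))
  invisible(x)
}

fmt_coord <- function(x) formatC(x, format = "d")

#' Write intervals as BED
#'
#' @param x interval `data.frame`.
#' @param path output path.
#' @return Invisibly, `path`. Writes BED4 (or BED6 when a strand column with
#'   stranded entries is present), tab-separated, no header.
#' @export
write_bed <- function(x, path) {
  stranded <- "strand" %in% names(x) && any(x$strand %in% c("+", "-"))
  cols <- if (stranded)
    cbind(x$chrom, fmt_coord(x$start), fmt_coord(x$end), x$name, "0", x$strand)
  else cbind(x$chrom, fmt_coord(x$start), fmt_coord(x$end), x$name)
  if (nrow(x) == 0) {
    writeLines(character(0), path)
  } else {
    utils::write.table(cols, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

annotation_columns <- c("chrom", "start", "end", "peak", "gene", "strand",
                        "expression", "Upstream", "5UTR", "Exon", "Intron",
                        "3UTR", "Downstream", "warning")

#' Write an annotation table
#'
#' One row per annotated (genic) peak: coordinates, peak name, assigned gene
#' and its strand and expression value, the six feature flags (0/1) and the
#' warning flag (0/1). Intergenic peaks belong in a separate BED file
#' ([write_bed()]), not here.
#'
#' @param records annotation record `data.frame` (rows of an
#'   [annotate_peaks()] result's `records`).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(records, path) {
  out <- data.frame(
    chrom = records$chrom,
    start = fmt_coord(records$start),
    end = fmt_coord(records$end),
    peak = records$peak,
    gene = records$gene,
    strand = records$gene_strand,
    expression = records$expression,
    Upstream = as.integer(records$Upstream),
    X5UTR = as.integer(records$`5UTR`),
    Exon = as.integer(records$Exon),
    Intron = as.integer(records$Intron),
    X3UTR = as.integer(records$`3UTR`),
    Downstream = as.integer(records$Downstream),
    warning = as.integer(records$warning),
    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- annotation_columns
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# chromosomes present in peaks but absent from the reference sizes
chrom_mismatch <- function(peaks, chrom_sizes)
  setdiff(unique(peaks$chrom), names(chrom_sizes))
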