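#' Find genes overlapping each peak
#'
#' A peak is genic iff it shares at least 1 bp with any gene span extended
#' by its strand-aware upstream/downstream flanks; the peak's full
#' `[start, end)` extent is used, never its midpoint — this is what keeps
#' kilobase-scale R-loop peaks from being called intergenic when their
#' centre happens to fall between genes. Overlap search is indexed with
#' `GenomicRanges::findOverlaps()`.
#'
#' @param peaks interval `data.frame` of query peaks.
#' @param genes gene-model `data.frame` ([read_bed12()]).
#' @param up_size,down_size flank sizes in bp.
#' @param chrom_sizes named numeric vector of chromosome lengths; flank
#'   extensions are clamped to them. Peaks on chromosomes absent from it
#'   are reported in `mismatch` and classed intergenic.
#' @return A list: `hits` — `data.frame` with one row per (peak, gene
#'   record) overlap, columns `peak` and `gene` (row indices into the
#'   inputs), `overlap_bp` (overlap with the flank-extended span, >= 1)
#'   and `body_overlap_bp` (overlap with the unextended span); `genic` and
#'   `intergenic` — disjoint index vectors partitioning the peaks;
#'   `mismatch` — chromosome names present in peaks but not in
#'   `chrom_sizes`.
#' @export
find_overlaps <- function(peaks, genes, up_size = 5000, down_size = 5000,
                          chrom_sizes = NULL) {
  validate_intervals(peaks, "peak")
  n <- nrow(peaks)
  mismatch <- if (is.null(chrom_sizes)) character(0)
              else chrom_mismatch(peaks, chrom_sizes)
  empty_hits <- data.frame(peak = integer(0), gene = integer(0),
                           overlap_bp = numeric(0), body_overlap_bp = numeric(0))
  if (n == 0 || nrow(genes) == 0)
    return(list(hits = empty_hits, genic = integer(0),
                intergenic = seq_len(n), mismatch = mismatch))

  ext <- extended_spans(genes, up_size, down_size, chrom_sizes)
  eligible <- which(!(peaks$chrom %in% mismatch))
  pk <- GenomicRanges::GRanges(peaks$chrom[eligible],
                               IRanges::IRanges(peaks$start[eligible] + 1,
                                                peaks$end[eligible]))
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(ext$start + 1, ext$end))
  ov <- GenomicRanges::findOverlaps(pk, gn, minoverlap = 1L,
                                    ignore.strand = TRUE)
  pi <- eligible[S4Vectors::queryHits(ov)]
  gi <- S4Vectors::subjectHits(ov)
  hits <- data.frame(
    peak = pi, gene = gi,
    overlap_bp = .ov_len(peaks$start[pi], peaks$end[pi],
                         ext$start[gi], ext$end[gi]),
    body_overlap_bp = .ov_len(peaks$start[pi], peaks$end[pi],
                              genes$start[gi], genes$end[gi]))
  genic <- sort(unique(hits$peak))
  list(hits = hits, genic = genic,
       intergenic = setdiff(seq_len(n), genic), mismatch = mismatch)
}

# Flank-extended span of every gene record, clamped to chromosome bounds.
extended_spans <- function(genes, up_size, down_size, chrom_sizes = NULL) {
  plus <- genes$strand == "+"
  s <- genes$start - ifelse(plus, up_size, down_size)
  e <- genes$end + ifelse(plus, down_size, up_size)
  s <- pmax(0, s)
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes[genes$chrom]
    len[is.na(len)] <- Inf
    # never clamp into the gene body itself, even if sizes are inconsistent
    e <- pmax(pmin(e, len), genes$end)
  }
  data.frame(start = s, end = e)
}
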