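FEATURE_NAMES <- c("Upstream", "5UTR", "Exon", "Intron", "3UTR", "Downstream")
BODY_FEATURES <- c("5UTR", "Exon", "Intron", "3UTR")

#' Template strand of a gene
#'
#' R-loops form co-transcriptionally: the nascent RNA anneals back to the
#' DNA template strand, which is the complement of the gene's annotated
#' strand. Assigning a peak to a gene therefore fixes the strand of its
#' DNA:RNA hybrid.
#'
#' @param gene_strand `"+"` or `"-"` (the annotated/coding strand).
#' @return The complementary strand. `"."` or anything else is an error.
#' @export
template_strand <- function(gene_strand) {
  out <- c("+" = "-", "-" = "+")[gene_strand]
  if (any(is.na(out)))
    stop("template strand undefined for strand '",
         gene_strand[is.na(out)][1], "'", call. = FALSE)
  unname(out)
}

#' Select the annotated gene for a peak
#'
#' Resolution order, following the expression-first rule: a single
#' candidate wins outright; otherwise the gene with the highest
#' above-threshold expression wins; when no candidate is expressed, all
#' expressed candidates tie, or no expression data were given, the gene
#' with the largest overlap (flank-extended span) wins. Remaining ties are
#' broken by the lexicographically smallest gene name, so selection is a
#' total order and runs are deterministic.
#'
#' @param hits `data.frame` with one row per candidate gene record, columns
#'   `gene_name` and `overlap_bp` (rows of [find_overlaps()] `hits` for one
#'   peak, with names attached).
#' @param expression named numeric vector (may be empty = no expression
#'   mode). Genes absent from it count as expression 0.
#' @param threshold genes with value strictly above this are "expressed".
#' @return List: `index` (chosen row of `hits`), `reason` (one of
#'   `"single_gene"`, `"highest_expression"`, `"largest_overlap"`),
#'   `expressed` (is the chosen gene's value above threshold), `value`
#'   (its expression value).
#' @export
select_gene <- function(hits, expression = NULL, threshold = 0) {
  stopifnot(nrow(hits) >= 1)
  if (is.null(expression)) expression <- stats::setNames(numeric(0), character(0))
  vals <- unname(expression[hits$gene_name])
  vals[is.na(vals)] <- 0
  sel <- .select_idx(hits$gene_name, hits$overlap_bp, vals,
                     expr_mode = length(expression) > 0,
                     threshold = threshold)
  list(index = sel$index, reason = sel$reason,
       expressed = vals[sel$index] > threshold, value = vals[sel$index])
}

# selection core on bare vectors (shared by select_gene and the annotate
# hot loop)
.select_idx <- function(names, ovl, vals, expr_mode, threshold) {
  pick_by_overlap <- function(rows) {
    rows <- rows[ovl[rows] == max(ovl[rows])]
    if (length(rows) > 1) rows <- rows[order(names[rows])]
    rows[1]
  }
  n_names <- length(unique(names))
  if (n_names == 1)
    return(list(index = pick_by_overlap(seq_along(names)),
                reason = "single_gene"))
  above <- which(vals > threshold)
  if (expr_mode && length(above)) {
    top <- above[vals[above] == max(vals[above])]
    if (length(unique(names[top])) == 1)
      return(list(index = pick_by_overlap(top), reason = "highest_expression"))
    return(list(index = pick_by_overlap(top), reason = "largest_overlap"))
  }
  list(index = pick_by_overlap(seq_along(names)), reason = "largest_overlap")
}

#' Feature flags for a peak against its assigned gene
#'
#' Long R-loop peaks routinely span several gene features, so the flags are
#' not mutually exclusive: each is true iff the peak shares at least 1 bp
#' with that feature of the assigned gene.
#'
#' @param peak single-row interval `data.frame`.
#' @param fs `feature_set` of the assigned gene with flanks filled in
#'   (see [derive_features()] / [flank_regions()]).
#' @return Named logical vector over `Upstream`, `5UTR`, `Exon`, `Intron`,
#'   `3UTR`, `Downstream`.
#' @export
assign_features <- function(peak, fs) {
  hit <- function(tab) {
    nrow(tab) > 0 && any(tab$chrom == peak$chrom[1] &
                           tab$start < peak$end[1] & tab$end > peak$start[1])
  }
  c(Upstream = hit(fs$upstream), "5UTR" = hit(fs$utr5), Exon = hit(fs$exons),
    Intron = hit(fs$introns), "3UTR" = hit(fs$utr3),
    Downstream = hit(fs$downstream))
}

#' Ambiguity warning for an annotation record
#'
#' Flags the two situations where an antisense R-loop could masquerade as
#' the assigned gene's: (a) the peak touches only the upstream and/or
#' downstream flank of its gene, where antisense transcription is common;
#' (b) the peak overlaps two or more genes that are all expressed above
#' threshold, so expression cannot arbitrate confidently.
#'
#' @param features named logical vector from [assign_features()].
#' @param n_expressed_genes number of distinct gene names overlapping the
#'   peak whose expression exceeds the threshold.
#' @return Logical.
#' @export
warn_flag <- function(features, n_expressed_genes) {
  flank_only <- !any(features[BODY_FEATURES]) &&
    any(features[c("Upstream", "Downstream")])
  flank_only || n_expressed_genes >= 2
}

#' Annotate R-loop peaks to genes and template strands
#'
#' The full annotation pass: find all genes whose flank-extended spans
#' overlap each peak, pick one gene per peak by expression (then by
#' overlap), derive the DNA template strand as the complement of the gene
#' strand, flag which gene features the peak covers, and mark ambiguous
#' placements. Peaks overlapping no extended gene span are returned
#' separately as intergenic.
#'
#' @param peaks interval `data.frame` or path to a BED file of peaks.
#' @param reference an `rloop_reference` (see [load_reference()]), a path
#'   to a reference folder, or a list with `genes`, `chrom_sizes` and
#'   optionally `features`.
#' @param expression named numeric vector, path to a 2-column expression
#'   table, or `NULL` for no-expression mode (selection is then purely by
#'   largest overlap and every record is classed unexpressed).
#' @param up_size,down_size flank sizes in bp (default 5000, the
#'   conventional promoter/terminator neighbourhood for R-loop work).
#' @param expression_threshold a gene is "expressed" when its value is
#'   strictly above this (default 0).
#' @return An object of class `rloop_annotation`: `records` (one row per
#'   genic peak: coordinates, `peak`, `gene`, `gene_strand`,
#'   `template_strand`, `expression`, `expressed`, the six feature flags,
#'   `warning`, `reason`, `rivals`), `intergenic` (interval `data.frame`),
#'   `mismatch` (peak chromosomes missing from the reference), `params`,
#'   and `n_input`. Deterministic: identical inputs give identical output.
#' @seealso [split_tables()], [feature_enrichment()], [render_reports()]
#' @export
annotate_peaks <- function(peaks, reference, expression = NULL,
                           up_size = 5000, down_size = 5000,
                           expression_threshold = 0) {
  if (is.character(peaks)) peaks <- read_bed(peaks)
  if (is.character(reference)) reference <- load_reference(reference)
  if (is.character(expression)) expression <- read_expression_table(expression)
  if (is.null(expression)) expression <- stats::setNames(numeric(0), character(0))
  validate_intervals(peaks, "peak")
  genes <- reference$genes
  sizes <- reference$chrom_sizes

  fo <- find_overlaps(peaks, genes, up_size, down_size, sizes)
  params <- list(up_size = up_size, down_size = down_size,
                 expression_threshold = expression_threshold,
                 expression_mode = length(expression) > 0)

  gene_vals <- unname(expression[genes$name])
  gene_vals[is.na(gene_vals)] <- 0
  expr_mode <- length(expression) > 0
  # per-gene feature intervals as bare matrices, filled lazily
  fs_cache <- vector("list", nrow(genes))
  feature_mats <- function(gi) {
    len <- sizes[genes$chrom[gi]]
    fs <- gene_feature_set(genes[gi, ], features = reference$features,
                           up_size = up_size, down_size = down_size,
                           chrom_len = if (is.na(len)) Inf else len)
    lapply(fs[c("upstream", "utr5", "exons", "introns", "utr3",
                "downstream")],
           function(tab) cbind(tab$start, tab$end))
  }

  hp <- fo$hits$peak
  hg <- fo$hits$gene
  hov <- fo$hits$overlap_bp
  hname <- genes$name[hg]
  hit_rows <- split(seq_along(hp), hp)
  ng <- length(fo$genic)
  r_gene_idx <- integer(ng)
  r_value <- numeric(ng)
  r_reason <- character(ng)
  r_flags <- matrix(FALSE, ng, 6, dimnames = list(NULL, FEATURE_NAMES))
  r_warn <- logical(ng)
  r_rivals <- character(ng)
  for (k in seq_len(ng)) {
    p <- fo$genic[k]
    rows <- hit_rows[[k]]
    sel <- .select_idx(hname[rows], hov[rows], gene_vals[hg[rows]],
                       expr_mode, expression_threshold)
    gi <- hg[rows][sel$index]
    if (is.null(fs_cache[[gi]])) fs_cache[[gi]] <- feature_mats(gi)
    ps <- peaks$start[p]; pe <- peaks$end[p]
    flags <- vapply(fs_cache[[gi]], function(m)
      nrow(m) > 0 && any(m[, 1] < pe & m[, 2] > ps), TRUE)
    expressed_names <- unique(hname[rows][gene_vals[hg[rows]] > expression_threshold])
    r_gene_idx[k] <- gi
    r_value[k] <- gene_vals[gi]
    r_reason[k] <- sel$reason
    r_flags[k, ] <- flags
    r_warn[k] <- (!any(flags[2:5]) && any(flags[c(1, 6)])) ||
      length(expressed_names) >= 2
    rv <- setdiff(expressed_names, genes$name[gi])
    r_rivals[k] <- if (length(rv)) paste(sort(rv), collapse = ",") else ""
  }
  records <- if (ng) data.frame(
    chrom = peaks$chrom[fo$genic], start = peaks$start[fo$genic],
    end = peaks$end[fo$genic], peak = peaks$name[fo$genic],
    gene = genes$name[r_gene_idx], gene_strand = genes$strand[r_gene_idx],
    template_strand = template_strand(genes$strand[r_gene_idx]),
    expression = r_value, expressed = r_value > expression_threshold,
    Upstream = r_flags[, 1], "5UTR" = r_flags[, 2], Exon = r_flags[, 3],
    Intron = r_flags[, 4], "3UTR" = r_flags[, 5], Downstream = r_flags[, 6],
    warning = r_warn, reason = r_reason, rivals = r_rivals,
    check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL)
  else empty_records()
  structure(list(records = records,
                 intergenic = peaks[fo$intergenic, , drop = FALSE],
                 mismatch = fo$mismatch, params = params,
                 n_input = nrow(peaks)),
            class = "rloop_annotation")
}

empty_records <- function() {
  r <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                  peak = character(0), gene = character(0),
                  gene_strand = character(0), template_strand = character(0),
                  expression = numeric(0), expressed = logical(0),
                  Upstream = logical(0), "5UTR" = logical(0),
                  Exon = logical(0), Intron = logical(0), "3UTR" = logical(0),
                  Downstream = logical(0), warning = logical(0),
                  reason = character(0), rivals = character(0),
                  check.names = FALSE, stringsAsFactors = FALSE)
  r
}

#' Split annotation records by expression class
#'
#' @param x an `rloop_annotation` or its `records` `data.frame`.
#' @return List of record `data.frame`s: `expressed` (assigned gene above
#'   threshold), `unexpressed` (the complement — in no-expression mode this
#'   is everything), `merged` (all records in input order). The two classes
#'   partition `merged`.
#' @export
split_tables <- function(x) {
  records <- if (inherits(x, "rloop_annotation")) x$records else x
  list(expressed = records[records$expressed, , drop = FALSE],
       unexpressed = records[!records$expressed, , drop = FALSE],
       merged = records)
}

#' @export
print.rloop_annotation <- function(x, ...) {
  cat(sprintf("R-loop peak annotation: %d peaks (%d genic, %d intergenic)\n",
              x$n_input, nrow(x$records), nrow(x$intergenic)))
  if (x$params$expression_mode)
    cat(sprintf("  expressed/unexpressed: %d/%d (threshold %g)\n",
                sum(x$records$expressed), sum(!x$records$expressed),
                x$params$expression_threshold))
  else cat("  no expression table: selection by largest overlap only\n")
  cat(sprintf("  warned (ambiguous) peaks: %d\n", sum(x$records$warning)))
  if (length(x$mismatch))
    cat("  chromosomes missing from reference: ",
        paste(x$mismatch, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.rloop_annotation <- function(object, ...) {
  counts <- count_features(object$records, object$intergenic)
  structure(list(n_input = object$n_input, n_genic = nrow(object$records),
                 n_intergenic = nrow(object$intergenic),
                 n_expressed = sum(object$records$expressed),
                 n_warned = sum(object$records$warning),
                 feature_counts = counts,
                 reasons = table(object$records$reason),
                 params = object$params),
            class = "summary.rloop_annotation")
}

#' @export
print.summary.rloop_annotation <- function(x, ...) {
  cat(sprintf("Peaks: %d input, %d genic, %d intergenic, %d warned\n",
              x$n_input, x$n_genic, x$n_intergenic, x$n_warned))
  cat("Selection reasons:\n")
  print(x$reasons)
  cat("Peaks overlapping each feature (not mutually exclusive):\n")
  print(x$feature_counts)
  invisible(x)
}

#' @export
as.data.frame.rloop_annotation <- function(x, ...) x$records
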