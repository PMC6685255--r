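#' Decompose a gene model into features
#'
#' Splits one BED12 gene record into its 5'UTR, exon, intron and 3'UTR
#' intervals. Exons come from the block structure; introns are the gaps
#' between consecutive blocks, so exons and introns tile the gene span
#' exactly. UTRs are the exonic complement of the CDS (thick region):
#' on the `+` strand the 5'UTR is every exonic base strictly before
#' `thick_start` and the 3'UTR every exonic base at or past `thick_end`;
#' on the `-` strand the two swap. Non-coding genes
#' (`thick_start == thick_end`) and genes whose CDS covers the whole span
#' have empty UTRs.
#'
#' @param gene single-row gene-model `data.frame` (a row of
#'   [read_bed12()] output).
#' @param features optional named list of per-feature interval tables
#'   (from a reference folder); when supplied, features for this gene are
#'   looked up by name there instead of being derived.
#' @return A list of class `feature_set`: `gene_name` plus interval tables
#'   `utr5`, `utr3`, `exons`, `introns`, `upstream`, `downstream` (flanks
#'   are empty here; see [flank_regions()]).
#' @examples
#' g <- data.frame(chrom = "chr1", start = 100, end = 1000, name = "gene1",
#'                 score = 0, strand = "+", thick_start = 200, thick_end = 800,
#'                 block_count = 2)
#' g$block_sizes <- list(c(200, 300))
#' g$block_starts <- list(c(0, 600))
#' derive_features(g)
#' @export
derive_features <- function(gene, features = NULL) {
  check_gene_model(gene)
  chrom <- gene$chrom[1]
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  iv <- function(s, e) {
    keep <- e > s
    data.frame(chrom = rep(chrom, sum(keep)), start = s[keep], end = e[keep])
  }
  if (!is.null(features)) {
    pick <- function(tab) {
      sub <- tab[tab$name == gene$name[1] & tab$chrom == chrom, , drop = FALSE]
      iv(sub$start, sub$end)
    }
    out <- list(gene_name = gene$name[1],
                utr5 = pick(features$utr5), utr3 = pick(features$utr3),
                exons = pick(features$exons), introns = pick(features$introns),
                upstream = empty, downstream = empty)
    return(structure(out, class = "feature_set"))
  }
  ex_s <- gene$start[1] + gene$block_starts[[1]]
  ex_e <- ex_s + gene$block_sizes[[1]]
  exons <- iv(ex_s, ex_e)
  introns <- if (length(ex_s) > 1) iv(ex_e[-length(ex_e)], ex_s[-1]) else empty
  ts <- gene$thick_start[1]; te <- gene$thick_end[1]
  clip <- function(lo, hi)  # exonic bases within [lo, hi)
    iv(pmax(ex_s, lo), pmin(ex_e, hi))
  if (ts == te) {
    left <- empty; right <- empty
  } else {
    left <- clip(gene$start[1], ts)   # exonic bases before the CDS
    right <- clip(te, gene$end[1])    # exonic bases after the CDS
  }
  plus <- gene$strand[1] == "+"
  structure(list(gene_name = gene$name[1],
                 utr5 = if (plus) left else right,
                 utr3 = if (plus) right else left,
                 exons = exons, introns = introns,
                 upstream = empty, downstream = empty),
            class = "feature_set")
}

#' Strand-aware flanking regions of a gene
#'
#' The upstream flank abuts the gene's 5' boundary and the downstream flank
#' its 3' boundary, so on the `-` strand upstream lies to the right of the
#' gene. Flanks are clamped to `[0, chrom_len)`; zero-width flanks (size 0,
#' or a gene at a chromosome edge) come back empty.
#'
#' @param gene single-row gene-model `data.frame`.
#' @param up_size,down_size flank sizes in bp (>= 0).
#' @param chrom_len chromosome length in bp (`Inf` to disable clamping).
#' @return List with interval tables `upstream` and `downstream`.
#' @export
flank_regions <- function(gene, up_size = 5000, down_size = 5000,
                          chrom_len = Inf) {
  stopifnot(up_size >= 0, down_size >= 0)
  chrom <- gene$chrom[1]
  iv <- function(s, e) {
    s <- max(0, s); e <- min(chrom_len, e)
    if (e > s) data.frame(chrom = chrom, start = s, end = e)
    else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  }
  if (gene$strand[1] == "+") {
    list(upstream = iv(gene$start[1] - up_size, gene$start[1]),
         downstream = iv(gene$end[1], gene$end[1] + down_size))
  } else {
    list(upstream = iv(gene$end[1], gene$end[1] + up_size),
         downstream = iv(gene$start[1] - down_size, gene$start[1]))
  }
}

# Full feature set for one gene, flanks included.
gene_feature_set <- function(gene, features = NULL, up_size = 5000,
                             down_size = 5000, chrom_len = Inf) {
  fs <- derive_features(gene, features = features)
  fl <- flank_regions(gene, up_size, down_size, chrom_len)
  fs$upstream <- fl$upstream
  fs$downstream <- fl$downstream
  fs
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set for gene '%s'\n", x$gene_name))
  for (f in c("upstream", "utr5", "exons", "introns", "utr3", "downstream"))
    cat(sprintf("  %-10s %d interval(s), %s bp\n", f, nrow(x[[f]]),
                fmt_coord(sum(x[[f]]$end - x[[f]]$start))))
  invisible(x)
}
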