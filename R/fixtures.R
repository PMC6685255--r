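#' Specification for a synthetic annotation fixture
#'
#' Describes a small synthetic genome with gene models, an expression
#' table, and peaks of known placement class, emulating the shape of a
#' DRIP-seq validation set: kilobase-scale peaks, multi-exon genes with a
#' realistic TPM dynamic range, silent genes, and deliberately ambiguous
#' placements (flank-only peaks, peaks across two overlapping expressed
#' genes) whose expected annotation is recorded alongside the inputs.
#'
#' @param n_chroms,chrom_len number and length (bp) of chromosomes.
#' @param n_genes number of gene models; pairs demanded by the
#'   `two_gene_overlap` class are carved from this total, everything else
#'   is placed non-overlapping with disjoint flank territories.
#' @param gene_len_range,exon_count_range per-gene span and exon-count
#'   ranges (uniform).
#' @param expressed_fraction fraction of single genes given non-zero
#'   expression; silent genes get exactly 0.
#' @param expression_range bounds of the log-uniform expression law for
#'   expressed genes (default 0.1–1000, a realistic TPM range).
#' @param noncoding_fraction fraction of single genes made non-coding
#'   (degenerate thick region, hence no UTRs).
#' @param peak_classes named counts for placement classes `gene_body`,
#'   `flank_only`, `two_gene_overlap`, `intergenic`.
#' @param peak_len_range peak length range in bp.
#' @param up_size,down_size,expression_threshold annotation parameters the
#'   recorded truth assumes.
#' @param seed integer; generation is fully deterministic given the spec.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_chroms = 2, chrom_len = 1e6, n_genes = 40,
                         gene_len_range = c(2000, 15000),
                         exon_count_range = c(1, 6),
                         expressed_fraction = 0.7,
                         expression_range = c(0.1, 1000),
                         noncoding_fraction = 0.1,
                         peak_classes = c(gene_body = 120, flank_only = 30,
                                          two_gene_overlap = 20,
                                          intergenic = 30),
                         peak_len_range = c(200, 3000),
                         up_size = 5000, down_size = 5000,
                         expression_threshold = 0, seed = 1) {
  classes <- c(gene_body = 0, flank_only = 0, two_gene_overlap = 0,
               intergenic = 0)
  classes[names(peak_classes)] <- peak_classes
  stopifnot(all(classes >= 0), n_genes >= 1, n_chroms >= 1,
            expressed_fraction >= 0, expressed_fraction <= 1)
  structure(list(n_chroms = n_chroms, chrom_len = chrom_len,
                 n_genes = n_genes, gene_len_range = gene_len_range,
                 exon_count_range = exon_count_range,
                 expressed_fraction = expressed_fraction,
                 expression_range = expression_range,
                 noncoding_fraction = noncoding_fraction,
                 peak_classes = classes, peak_len_range = peak_len_range,
                 up_size = up_size, down_size = down_size,
                 expression_threshold = expression_threshold, seed = seed),
            class = "fixture_spec")
}

# integer partition of `total` into `parts` pieces, each >= min_each
rand_partition <- function(total, parts, min_each) {
  if (parts == 1) return(total)
  spare <- total - parts * min_each
  stopifnot(spare >= 0)
  w <- stats::runif(parts)
  extra <- floor(spare * w / sum(w))
  extra[1] <- extra[1] + spare - sum(extra)
  min_each + extra
}

# one gene-model row; list-columns filled by the caller
make_gene <- function(spec, chrom, start, len, name, strand, coding) {
  min_exon <- 100; min_intron <- 50
  k <- sample(seq(spec$exon_count_range[1], spec$exon_count_range[2]), 1)
  while (k > 1 && len < k * min_exon + (k - 1) * min_intron) k <- k - 1
  exon_total <- if (k == 1) len else {
    lo <- k * min_exon
    hi <- len - (k - 1) * min_intron
    round(lo + (hi - lo) * stats::runif(1, 0.3, 0.7))
  }
  sizes <- rand_partition(exon_total, k, min_exon)
  gaps <- if (k > 1) rand_partition(len - exon_total, k - 1, min_intron) else numeric(0)
  starts <- cumsum(c(0, sizes[-k] + gaps))
  if (coding) {
    # CDS starts inside the first exon and ends inside the last, so both
    # UTRs are non-empty
    ts <- start + starts[1] + sample(seq(1, sizes[1] - 1), 1)
    te <- start + starts[k] + sample(seq(1, sizes[k] - 1), 1)
    if (k == 1) {
      pts <- sort(sample(seq(1, sizes[1] - 1), 2))
      ts <- start + pts[1]; te <- start + pts[2]
    }
    if (ts > te) { tmp <- ts; ts <- te; te <- tmp }
    if (ts == te) te <- te + 1
  } else {
    ts <- start; te <- start
  }
  g <- data.frame(chrom = chrom, start = start, end = start + len,
                  name = name, score = 0, strand = strand,
                  thick_start = ts, thick_end = te, block_count = k,
                  stringsAsFactors = FALSE)
  g$block_sizes <- list(sizes)
  g$block_starts <- list(starts)
  g
}

# Independent per-gene feature arithmetic used only to record ground
# truth; deliberately straight-line code over the block layout.
truth_flags <- function(ps, pe, g, up, down, chrom_len) {
  ov <- function(s, e) any(pmax(ps, s) < pmin(pe, e))
  ex_s <- g$start + g$block_starts[[1]]
  ex_e <- ex_s + g$block_sizes[[1]]
  exon <- ov(ex_s, ex_e)
  intron <- length(ex_s) > 1 && ov(ex_e[-length(ex_e)], ex_s[-1])
  ts <- g$thick_start; te <- g$thick_end
  left <- right <- FALSE
  if (ts < te) {
    ls <- pmax(ex_s, g$start); le <- pmin(ex_e, ts)
    left <- any(pmax(ps, ls[le > ls]) < pmin(pe, le[le > ls]))
    rs <- pmax(ex_s, te); re <- pmin(ex_e, g$end)
    right <- any(pmax(ps, rs[re > rs]) < pmin(pe, re[re > rs]))
  }
  if (g$strand == "+") {
    upstream <- ov(max(0, g$start - up), g$start)
    downstream <- ov(g$end, min(chrom_len, g$end + down))
    utr5 <- left; utr3 <- right
  } else {
    upstream <- ov(g$end, min(chrom_len, g$end + up))
    downstream <- ov(max(0, g$start - down), g$start)
    utr5 <- right; utr3 <- left
  }
  c(Upstream = upstream, "5UTR" = isTRUE(utr5), Exon = exon,
    Intron = isTRUE(intron), "3UTR" = isTRUE(utr3), Downstream = downstream)
}

#' Generate a synthetic annotation fixture
#'
#' Builds the five artifacts of a test data set — peaks BED, genes BED12,
#' expression TSV, chrom.sizes, and a ground-truth table recording every
#' peak's expected gene, template strand, feature flags, warning and
#' expression class. Placement guarantees: single genes have disjoint
#' flank-extended territories; overlapping pairs (for the
#' `two_gene_overlap` class) are both expressed with distinct values, so
#' their expected winner is the higher-expressed gene; intergenic peaks sit
#' in zones no extended gene span reaches.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, `peaks.bed`, `genes.bed12`,
#'   `expression.tsv`, `chrom.sizes` and `truth.tsv` are written there.
#' @return List of class `rloop_fixture`: `peaks`, `genes`, `expression`,
#'   `chrom_sizes`, `truth`, `spec`, `dir`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  out <- with_seed(spec$seed, build_fixture(spec))
  out$dir <- dir
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_bed(out$peaks, file.path(dir, "peaks.bed"))
    write_bed12(out$genes, file.path(dir, "genes.bed12"))
    writeLines(paste(names(out$expression), out$expression, sep = "\t"),
               file.path(dir, "expression.tsv"))
    writeLines(paste(names(out$chrom_sizes),
                     fmt_coord(out$chrom_sizes), sep = "\t"),
               file.path(dir, "chrom.sizes"))
    write_tsv(out$truth, file.path(dir, "truth.tsv"))
  }
  out
}

build_fixture <- function(spec) {
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  chrom_sizes <- stats::setNames(rep(spec$chrom_len, spec$n_chroms), chroms)
  flank <- max(spec$up_size, spec$down_size)
  free_gap <- 3000

  n_pairs <- if (spec$peak_classes[["two_gene_overlap"]] > 0)
    max(1, ceiling(spec$peak_classes[["two_gene_overlap"]] / 10)) else 0
  if (2 * n_pairs > spec$n_genes)
    stop("fixture spec unsatisfiable: not enough genes for overlap pairs",
         call. = FALSE)
  n_singles <- spec$n_genes - 2 * n_pairs

  cursor <- stats::setNames(rep(2000, spec$n_chroms), chroms)
  free_zones <- list()
  genes <- list()
  pairs <- list()      # row-index pairs into `genes`
  singles <- integer(0)
  gid <- 0

  place_unit <- function(unit_len) {
    # returns c(chrom, unit_start) or NULL
    need <- free_gap + flank + unit_len + flank
    ok <- chroms[cursor + need <= spec$chrom_len - 4000]
    if (!length(ok)) return(NULL)
    ch <- ok[which.min(cursor[ok])]
    c(ch, cursor[[ch]] + free_gap + flank)
  }
  units <- c(rep("pair", n_pairs), rep("single", n_singles))
  for (u in units) {
    if (u == "pair") {
      la <- round(stats::runif(1, spec$gene_len_range[1], spec$gene_len_range[2]))
      lb <- round(stats::runif(1, spec$gene_len_range[1], spec$gene_len_range[2]))
      ovl <- sample(500:min(2000, floor(min(la, lb) / 3)), 1)
      lb <- max(lb, ovl + 500)
      unit_len <- la + lb - ovl
    } else {
      la <- round(stats::runif(1, spec$gene_len_range[1], spec$gene_len_range[2]))
      unit_len <- la
    }
    at <- place_unit(unit_len)
    if (is.null(at))
      stop("fixture spec unsatisfiable: genes do not fit the chromosomes",
           call. = FALSE)
    ch <- at[1]; us <- as.numeric(at[2])
    zone <- c(cursor[[ch]] + 100, us - flank - 100)
    if (diff(zone) >= 1500) free_zones[[length(free_zones) + 1]] <-
      list(chrom = ch, start = zone[1], end = zone[2])
    if (u == "pair") {
      ga <- make_gene(spec, ch, us, la, sprintf("gene_%03d", gid + 1),
                      sample(c("+", "-"), 1), coding = TRUE)
      gb <- make_gene(spec, ch, us + la - ovl, lb,
                      sprintf("gene_%03d", gid + 2),
                      sample(c("+", "-"), 1), coding = TRUE)
      genes[[length(genes) + 1]] <- ga
      genes[[length(genes) + 1]] <- gb
      pairs[[length(pairs) + 1]] <- c(gid + 1, gid + 2)
      gid <- gid + 2
    } else {
      coding <- stats::runif(1) >= spec$noncoding_fraction
      g <- make_gene(spec, ch, us, la, sprintf("gene_%03d", gid + 1),
                     sample(c("+", "-"), 1), coding = coding)
      genes[[length(genes) + 1]] <- g
      singles <- c(singles, gid + 1)
      gid <- gid + 1
    }
    cursor[[ch]] <- us + unit_len + flank
  }
  for (ch in chroms)
    if (spec$chrom_len - 100 - (cursor[[ch]] + 100) >= 1500)
      free_zones[[length(free_zones) + 1]] <-
        list(chrom = ch, start = cursor[[ch]] + 100,
             end = spec$chrom_len - 100)
  genes <- do.call(rbind, genes)

  # expression: pair members always expressed with distinct values
  expr <- stats::setNames(rep(0, nrow(genes)), genes$name)
  draw_expr <- function(n) round(10 ^ stats::runif(
    n, log10(spec$expression_range[1]), log10(spec$expression_range[2])), 3)
  for (pr in pairs) {
    v <- draw_expr(2)
    while (v[1] == v[2]) v <- draw_expr(2)
    expr[pr] <- v
  }
  on_singles <- singles[stats::runif(length(singles)) < spec$expressed_fraction]
  expr[on_singles] <- draw_expr(length(on_singles))

  # peaks with recorded truth
  pk <- list(); tr <- list(); pid <- 0
  thr <- spec$expression_threshold
  add_peak <- function(ch, s, e, class, gene_row = NA, warn = FALSE,
                       reason = NA_character_) {
    pid <<- pid + 1
    name <- sprintf("peak_%04d", pid)
    pk[[pid]] <<- data.frame(chrom = ch, start = s, end = e, name = name,
                             strand = ".", stringsAsFactors = FALSE)
    if (is.na(gene_row)) {
      flags <- stats::setNames(rep(FALSE, 6), FEATURE_NAMES)
      tr[[pid]] <<- data.frame(peak = name, class = class,
                               gene = NA_character_,
                               template_strand = NA_character_,
                               t(flags), warning = FALSE, expressed = FALSE,
                               reason = reason, check.names = FALSE,
                               stringsAsFactors = FALSE)
    } else {
      g <- genes[gene_row, ]
      flags <- truth_flags(s, e, g, spec$up_size, spec$down_size,
                           chrom_sizes[[g$chrom]])
      tr[[pid]] <<- data.frame(peak = name, class = class, gene = g$name,
                               template_strand = template_strand(g$strand),
                               t(flags), warning = warn,
                               expressed = expr[[g$name]] > thr,
                               reason = reason, check.names = FALSE,
                               stringsAsFactors = FALSE)
    }
  }
  rand_len <- function(cap = Inf) {
    lo <- spec$peak_len_range[1]
    hi <- max(lo, min(spec$peak_len_range[2], cap))
    round(stats::runif(1, lo, hi))
  }
  nc <- spec$peak_classes
  if (nc[["gene_body"]] > 0 && !length(singles))
    stop("fixture spec unsatisfiable: gene_body peaks need single genes",
         call. = FALSE)
  for (i in seq_len(nc[["gene_body"]])) {
    gi <- sample(singles, 1)
    g <- genes[gi, ]
    len <- rand_len(g$end - g$start)
    s <- floor(stats::runif(1, g$start, g$end - len + 1))
    add_peak(g$chrom, s, s + len, "gene_body", gi, warn = FALSE,
             reason = "single_gene")
  }
  for (i in seq_len(nc[["flank_only"]])) {
    gi <- sample(singles, 1)
    g <- genes[gi, ]
    side <- sample(c("upstream", "downstream"), 1)
    sz <- if (side == "upstream") spec$up_size else spec$down_size
    fl <- if ((side == "upstream") == (g$strand == "+"))
      c(g$start - sz, g$start) else c(g$end, g$end + sz)
    len <- rand_len(diff(fl) - 20)
    s <- floor(stats::runif(1, fl[1] + 10, fl[2] - len - 9))
    add_peak(g$chrom, s, s + len, "flank_only", gi, warn = TRUE,
             reason = "single_gene")
  }
  for (i in seq_len(nc[["two_gene_overlap"]])) {
    pr <- pairs[[sample(length(pairs), 1)]]
    a <- genes[pr[1], ]; b <- genes[pr[2], ]
    s <- floor(stats::runif(1, max(a$start, b$start - 800), b$start))
    e <- ceiling(stats::runif(1, a$end + 1, min(b$end, a$end + 800)))
    winner <- pr[if (expr[[a$name]] >= expr[[b$name]]) 1 else 2]
    add_peak(a$chrom, s, e, "two_gene_overlap", winner, warn = TRUE,
             reason = "highest_expression")
  }
  if (nc[["intergenic"]] > 0 && !length(free_zones))
    stop("fixture spec unsatisfiable: no intergenic space left", call. = FALSE)
  for (i in seq_len(nc[["intergenic"]])) {
    z <- free_zones[[sample(length(free_zones), 1)]]
    len <- rand_len(min(1000, z$end - z$start - 10))
    s <- floor(stats::runif(1, z$start, z$end - len))
    add_peak(z$chrom, s, s + len, "intergenic")
  }
  peaks <- do.call(rbind, pk)
  truth <- do.call(rbind, tr)
  structure(list(peaks = peaks, genes = genes, expression = expr,
                 chrom_sizes = chrom_sizes, truth = truth, spec = spec),
            class = "rloop_fixture")
}

#' Write gene models as BED12
#'
#' @param genes gene-model `data.frame`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    paste(g$chrom, fmt_coord(g$start), fmt_coord(g$end), g$name, g$score,
          g$strand, fmt_coord(g$thick_start), fmt_coord(g$thick_end), "0",
          fmt_coord(g$block_count),
          paste0(paste(fmt_coord(g$block_sizes[[1]]), collapse = ","), ","),
          paste0(paste(fmt_coord(g$block_starts[[1]]), collapse = ","), ","),
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Score an annotation result against fixture ground truth
#'
#' A peak is fully correct when its assigned gene, template strand and all
#' six feature flags match the recorded truth (intergenic truth rows must
#' land in the intergenic output). Agreement is also broken down per
#' component and per placement class.
#'
#' @param annotation an `rloop_annotation` from the fixture's inputs.
#' @param truth the fixture's `truth` table.
#' @return List: `correct_fraction` (all components correct),
#'   `strand_fraction`, `gene_fraction`, `flags_fraction`,
#'   `warning_fraction`, `by_class` (`data.frame`), `per_peak`
#'   (`data.frame` of per-peak agreement).
#' @export
score_against_truth <- function(annotation, truth) {
  records <- annotation$records
  missing <- setdiff(truth$peak, c(records$peak, annotation$intergenic$name))
  if (length(missing))
    stop("peaks in truth but absent from annotation output: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  ri <- match(truth$peak, records$peak)
  is_int <- truth$peak %in% annotation$intergenic$name
  ok_gene <- ok_strand <- ok_flags <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (is.na(truth$gene[i])) {
      ok_gene[i] <- ok_strand[i] <- ok_flags[i] <- is_int[i]
    } else if (is.na(ri[i])) {
      ok_gene[i] <- ok_strand[i] <- ok_flags[i] <- FALSE
    } else {
      r <- records[ri[i], ]
      ok_gene[i] <- r$gene == truth$gene[i]
      ok_strand[i] <- r$template_strand == truth$template_strand[i]
      ok_flags[i] <- all(vapply(FEATURE_NAMES, function(f)
        isTRUE(r[[f]] == truth[[f]][i]), TRUE))
    }
  }
  ok_warn <- ifelse(is.na(ri), is_int & !truth$warning,
                    records$warning[ri] == truth$warning)
  all_ok <- ok_gene & ok_strand & ok_flags
  per_peak <- data.frame(peak = truth$peak, class = truth$class,
                         gene_ok = ok_gene, strand_ok = ok_strand,
                         flags_ok = ok_flags, warning_ok = ok_warn,
                         correct = all_ok, stringsAsFactors = FALSE)
  by_class <- do.call(rbind, lapply(split(per_peak, per_peak$class),
    function(d) data.frame(class = d$class[1], n = nrow(d),
                           correct = mean(d$correct),
                           stringsAsFactors = FALSE)))
  rownames(by_class) <- NULL
  list(correct_fraction = mean(all_ok),
       gene_fraction = mean(ok_gene),
       strand_fraction = mean(ok_strand),
       flags_fraction = mean(ok_flags),
       warning_fraction = mean(ok_warn),
       by_class = by_class, per_peak = per_peak)
}

#' @export
print.rloop_fixture <- function(x, ...) {
  cat(sprintf("Synthetic fixture: %d genes, %d peaks on %d chromosome(s) (seed %d)\n",
              nrow(x$genes), nrow(x$peaks), length(x$chrom_sizes),
              x$spec$seed))
  print(table(x$truth$class))
  invisible(x)
}
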