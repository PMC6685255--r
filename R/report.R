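PIE_PRIORITY <- c("5UTR", "3UTR", "Exon", "Intron", "Upstream", "Downstream")

#' Count exact feature combinations
#'
#' Tally of peaks by the exact set of feature flags they carry — the
#' numbers behind an upset-style plot of multi-feature peaks.
#'
#' @param records annotation record `data.frame`.
#' @return `data.frame` with `combo` (feature names joined by `+`, in
#'   Upstream..Downstream order) and `count`, sorted by decreasing count.
#'   Counts sum to the number of genic records.
#' @export
combo_counts <- function(records) {
  if (nrow(records) == 0)
    return(data.frame(combo = character(0), count = integer(0)))
  labels <- apply(as.matrix(records[, FEATURE_NAMES]), 1, function(f)
    paste(FEATURE_NAMES[as.logical(f)], collapse = "+"))
  tab <- sort(table(labels), decreasing = TRUE)
  data.frame(combo = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

# One label per peak for pie proportions: transcribed gene-body features
# take priority over flanks, flanks over intergenic.
pie_counts <- function(records, intergenic = NULL) {
  lab <- apply(as.matrix(records[, PIE_PRIORITY, drop = FALSE]), 1,
               function(f) PIE_PRIORITY[which(as.logical(f))[1]])
  counts <- vapply(PIE_PRIORITY, function(p) sum(lab == p), 0L)
  c(counts, Intergenic = if (is.null(intergenic)) 0L else nrow(intergenic))
}

feature_percentage_table <- function(records, intergenic = NULL) {
  counts <- count_features(records, intergenic)
  total <- nrow(records) + if (is.null(intergenic)) 0 else nrow(intergenic)
  data.frame(feature = names(counts), count = as.integer(counts),
             percent = if (total > 0) round(100 * counts / total, 2) else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

write_tsv <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write the full report folder for an annotation run
#'
#' Emits the three annotation tables (expressed / unexpressed / merged),
#' the intergenic BED, the warned-peaks table, the enrichment table, the
#' summary TSVs behind every figure, and the figures themselves (PNG +
#' SVG). The TSVs are canonical: every number shown in a figure can be
#' recomputed from them, so a missing plotting device degrades gracefully
#' to tables plus a warning.
#'
#' @param annotation an `rloop_annotation`.
#' @param out_dir output folder (created if needed).
#' @param enrichment optional `rloop_enrichment`.
#' @param figures emit figure files (default `TRUE`).
#' @return Invisibly, `out_dir`.
#' @export
render_reports <- function(annotation, out_dir, enrichment = NULL,
                           figures = TRUE) {
  dir.create(file.path(out_dir, "summary"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "figures"), showWarnings = FALSE)
  parts <- split_tables(annotation)
  for (v in names(parts))
    write_annotation_table(parts[[v]],
                           file.path(out_dir, paste0("annotation.", v, ".tsv")))
  write_bed(annotation$intergenic, file.path(out_dir, "intergenic.bed"))
  warned <- annotation$records[annotation$records$warning, , drop = FALSE]
  write_tsv(warned[, c("chrom", "start", "end", "peak", "gene", "gene_strand",
                       "expression", "reason", "rivals")],
            file.path(out_dir, "warned_peaks.tsv"))
  if (!is.null(enrichment))
    write_tsv(enrichment$table, file.path(out_dir, "enrichment.tsv"))

  variant_intergenic <- list(expressed = NULL, unexpressed = NULL,
                             merged = annotation$intergenic)
  for (v in names(parts)) {
    ig <- variant_intergenic[[v]]
    write_tsv(feature_percentage_table(parts[[v]], ig),
              file.path(out_dir, "summary", paste0("feature_counts.", v, ".tsv")))
    write_tsv(combo_counts(parts[[v]]),
              file.path(out_dir, "summary", paste0("combo_counts.", v, ".tsv")))
    pc <- pie_counts(parts[[v]], ig)
    write_tsv(data.frame(feature = names(pc), count = as.integer(pc),
                         proportion = if (sum(pc) > 0)
                           round(as.integer(pc) / sum(pc), 4) else 0),
              file.path(out_dir, "summary", paste0("pie_counts.", v, ".tsv")))
  }
  if (figures) {
    ok <- tryCatch({
      for (v in names(parts)) {
        ig <- variant_intergenic[[v]]
        emit_figure(file.path(out_dir, "figures", paste0("features.", v)),
                    function() plot_feature_bars(parts[[v]], ig, main = v))
        emit_figure(file.path(out_dir, "figures", paste0("pie.", v)),
                    function() plot_feature_pie(parts[[v]], ig, main = v))
        emit_figure(file.path(out_dir, "figures", paste0("combos.", v)),
                    function() plot_combo_upset(combo_counts(parts[[v]]),
                                                main = v))
      }
      if (!is.null(enrichment))
        emit_figure(file.path(out_dir, "figures", "enrichment"),
                    function() plot_enrichment_panel(enrichment$table))
      TRUE
    }, error = function(e) {
      warning("figure rendering failed (", conditionMessage(e),
              "); tables were still written")
      FALSE
    })
    invisible(ok)
  }
  invisible(out_dir)
}

# Byte-identical output across repeated runs takes two precautions with
# cairo devices: antialias = "none" (glyph rasterization independent of
# the font-cache state) and a discarded warm-up render per figure, so the
# kept render always starts from the same warm glyph cache.
emit_figure <- function(stem, draw, width = 7, height = 5) {
  render <- function(open, path) {
    open(path); draw(); grDevices::dev.off()
  }
  open_png <- function(path)
    grDevices::png(path, width = width * 100, height = height * 100,
                   res = 100, antialias = "none")
  open_svg <- function(path)
    grDevices::svg(path, width = width, height = height,
                   antialias = "none")
  scratch <- tempfile(fileext = ".png")
  render(open_png, scratch)
  unlink(scratch)
  render(open_png, paste0(stem, ".png"))
  render(open_svg, paste0(stem, ".svg"))
}

feature_cols <- function(n) grDevices::hcl.colors(n, "Dark 3")

plot_feature_bars <- function(records, intergenic = NULL, main = "") {
  tab <- feature_percentage_table(records, intergenic)
  if (all(tab$count == 0)) { plot.new(); graphics::title(main); return(invisible()) }
  cols <- feature_cols(nrow(tab))
  graphics::barplot(tab$percent, names.arg = tab$feature, col = cols,
                    las = 2, ylab = "% of peaks overlapping feature",
                    main = main)
  graphics::legend("topright", bty = "n", fill = cols,
                   legend = sprintf("%s (n=%d)", tab$feature, tab$count))
}

plot_feature_pie <- function(records, intergenic = NULL, main = "") {
  pc <- pie_counts(records, intergenic)
  pc <- pc[pc > 0]
  if (!length(pc)) { plot.new(); graphics::title(main); return(invisible()) }
  graphics::pie(pc, labels = sprintf("%s (n=%d)", names(pc), pc),
                col = feature_cols(length(pc)), main = main)
}

# bar panel on top, membership dot matrix below
plot_combo_upset <- function(combos, main = "", max_combos = 12) {
  if (nrow(combos) == 0) { plot.new(); graphics::title(main); return(invisible()) }
  combos <- utils::head(combos, max_combos)
  k <- nrow(combos)
  member <- sapply(seq_len(k), function(i)
    FEATURE_NAMES %in% strsplit(combos$combo[i], "+", fixed = TRUE)[[1]])
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  graphics::layout(matrix(1:2), heights = c(2.2, 1.3))
  graphics::par(mar = c(0.5, 9, 3, 1))
  bp <- graphics::barplot(combos$count, col = "grey35", ylab = "peaks",
                          main = main)
  graphics::text(bp, combos$count, labels = combos$count, pos = 1,
                 col = "white", cex = 0.8)
  graphics::par(mar = c(1, 9, 0.5, 1))
  graphics::plot(NA, xlim = range(bp) + c(-0.6, 0.6), ylim = c(0.5, 6.5),
                 axes = FALSE, xlab = "", ylab = "")
  graphics::axis(2, at = 6:1, labels = FEATURE_NAMES, las = 2, tick = FALSE)
  for (i in seq_len(k)) {
    on <- which(member[, i])
    graphics::points(rep(bp[i], 6), 6:1, pch = 21, cex = 1.4,
                     bg = ifelse(member[, i], "grey20", "grey90"),
                     col = "grey60")
    if (length(on) > 1)
      graphics::segments(bp[i], min(7 - on), bp[i], max(7 - on), lwd = 2,
                         col = "grey20")
  }
}

plot_enrichment_panel <- function(tab, main = "Feature enrichment vs shuffled peaks") {
  fold <- ifelse(is.finite(tab$fold), tab$fold, NA)
  se <- ifelse(tab$rand_mean > 0, tab$rand_sd / tab$rand_mean, NA)
  ylim <- c(0, max(1.2, (fold + se)[is.finite(fold + se)], na.rm = TRUE) * 1.15)
  bp <- graphics::barplot(fold, names.arg = tab$feature, las = 2,
                          col = feature_cols(nrow(tab)),
                          ylab = "fold enrichment (observed / shuffled mean)",
                          main = main, ylim = ylim)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  ok <- is.finite(fold) & is.finite(se) & se > 0
  graphics::arrows(bp[ok], fold[ok] - se[ok], bp[ok], fold[ok] + se[ok],
                   angle = 90, code = 3, length = 0.04)
  lab <- ifelse(tab$degenerate, "p=NA",
                paste0("p=", signif(tab$p_value, 2)))
  graphics::text(bp, ylim[2] * 0.97, lab, cex = 0.7, srt = 45)
}

#' @export
plot.rloop_annotation <- function(x, which = c("features", "pie", "combos"),
                                  ...) {
  which <- match.arg(which)
  parts <- split_tables(x)
  switch(which,
         features = plot_feature_bars(parts$merged, x$intergenic,
                                      main = "merged"),
         pie = plot_feature_pie(parts$merged, x$intergenic, main = "merged"),
         combos = plot_combo_upset(combo_counts(parts$merged),
                                   main = "merged"))
  invisible(x)
}
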