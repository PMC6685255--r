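#' Run the full annotation workflow
#'
#' Orchestrates the whole pass over one peak set: load the reference and
#' expression table, find overlaps, select genes, assign features, write
#' the three annotation tables plus intergenic BED and warned-peaks table,
#' optionally run the shuffle-null enrichment, and render summary tables
#' and figures. A run manifest (parameters, seed, input checksums) is
#' written so a run can be reproduced exactly; with the same seed two runs
#' produce byte-identical output folders.
#'
#' @param peaks path to the query peaks BED file.
#' @param reference path to the reference folder (see [load_reference()]).
#' @param out_dir output folder, created if needed.
#' @param expression optional path to the 2-column expression table.
#' @param up_size,down_size,expression_threshold see [annotate_peaks()].
#' @param n_shuffles shuffle replicates for enrichment; `0` skips
#'   enrichment entirely.
#' @param seed integer seed for the shuffles.
#' @param figures emit figures (PNG/SVG) as well as TSVs.
#' @param derive force feature derivation from BED12 (see
#'   [load_reference()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the `annotation` (`rloop_annotation`) and
#'   `enrichment` (`rloop_enrichment` or `NULL`).
#' @export
run_workflow <- function(peaks, reference, out_dir, expression = NULL,
                         up_size = 5000, down_size = 5000,
                         expression_threshold = 0, n_shuffles = 10,
                         seed = NULL, figures = TRUE, derive = FALSE,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  ref <- load_reference(reference, derive = derive)
  pk <- read_bed(peaks)
  expr <- read_expression_table(expression)
  say("loaded %d peaks, %d gene models (%.1fs)", nrow(pk), nrow(ref$genes),
      proc.time()[["elapsed"]] - t0)

  ann <- annotate_peaks(pk, ref, expr, up_size, down_size,
                        expression_threshold)
  if (length(ann$mismatch))
    say("note: %d peak chromosome(s) absent from reference: %s",
        length(ann$mismatch), paste(ann$mismatch, collapse = ", "))
  say("annotated: %d genic, %d intergenic, %d warned (%.1fs)",
      nrow(ann$records), nrow(ann$intergenic), sum(ann$records$warning),
      proc.time()[["elapsed"]] - t0)

  enr <- NULL
  if (n_shuffles >= 2) {
    enr <- feature_enrichment(pk, ref, expr, n_shuffles = n_shuffles,
                              seed = seed, up_size = up_size,
                              down_size = down_size,
                              expression_threshold = expression_threshold)
    say("enrichment over %d shuffles done (%.1fs)", n_shuffles,
        proc.time()[["elapsed"]] - t0)
  } else {
    say("enrichment skipped (n_shuffles = %d)", n_shuffles)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  render_reports(ann, out_dir, enrichment = enr, figures = figures)

  cfg <- c(peaks = peaks, reference = reference,
           expression = if (is.null(expression)) "" else expression,
           up_size = up_size, down_size = down_size,
           expression_threshold = expression_threshold,
           n_shuffles = n_shuffles,
           seed = if (is.null(seed)) "" else seed,
           package_version = as.character(utils::packageVersion("rloopann")))
  inputs <- c(peaks, file.path(reference, "genes.bed12"),
              file.path(reference, "chrom.sizes"),
              if (!is.null(expression)) expression)
  sums <- tools::md5sum(inputs[file.exists(inputs)])
  manifest <- rbind(data.frame(key = names(cfg), value = unname(cfg)),
                    data.frame(key = paste0("md5:", basename(names(sums))),
                               value = unname(sums)))
  write_tsv(manifest, file.path(out_dir, "run_manifest.tsv"))
  say("reports written to %s (%.1fs)", out_dir,
      proc.time()[["elapsed"]] - t0)
  invisible(list(annotation = ann, enrichment = enr))
}
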