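test_that("template strand is the complement of the gene strand", {
  expect_equal(template_strand("+"), "-")
  expect_equal(template_strand("-"), "+")
  expect_error(template_strand("."), "template strand")
})

test_that("gene selection follows expression first, then overlap, then name", {
  hits <- data.frame(gene_name = c("A", "B"), overlap_bp = c(100, 900))
  expr <- c(A = 10, B = 3)
  s <- select_gene(hits, expr, threshold = 0.5)
  expect_equal(hits$gene_name[s$index], "A")
  expect_equal(s$reason, "highest_expression")
  expect_true(s$expressed)

  # all below threshold: fall back to largest overlap
  s <- select_gene(hits, c(A = 0, B = 0), threshold = 0.5)
  expect_equal(hits$gene_name[s$index], "B")
  expect_equal(s$reason, "largest_overlap")
  expect_false(s$expressed)

  # exact expression and overlap tie: lexicographically smallest name
  tie <- data.frame(gene_name = c("B", "A"), overlap_bp = c(500, 500))
  s <- select_gene(tie, c(A = 7, B = 7), threshold = 0.5)
  expect_equal(tie$gene_name[s$index], "A")
  expect_equal(s$reason, "largest_overlap")

  # no expression table at all
  s <- select_gene(hits, NULL, threshold = 0)
  expect_equal(hits$gene_name[s$index], "B")
  expect_equal(s$reason, "largest_overlap")

  # single candidate wins outright whatever its expression
  s <- select_gene(hits[1, ], c(A = 0), threshold = 0.5)
  expect_equal(s$reason, "single_gene")

  # only one candidate above threshold: expression decides
  s <- select_gene(hits, c(A = 10, B = 0), threshold = 0.5)
  expect_equal(hits$gene_name[s$index], "A")
  expect_equal(s$reason, "highest_expression")

  expect_error(select_gene(hits[0, ], expr, 0))
})

test_that("feature flags mark every feature the peak touches", {
  g <- two_exon_gene("+")
  fs <- derive_features(g)
  fl <- flank_regions(g, 5000, 5000, 1e6)
  fs$upstream <- fl$upstream
  fs$downstream <- fl$downstream

  # peak across the whole gene plus both flanks: all six flags
  all6 <- assign_features(genomic_intervals("chr1", 0, 7000), fs)
  expect_true(all(all6))

  # peak wholly inside the intron
  only_int <- assign_features(genomic_intervals("chr1", 350, 650), fs)
  expect_equal(unname(only_int),
               c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))

  # peak over the 3' end: exon, 3'UTR and downstream together
  mix <- assign_features(genomic_intervals("chr1", 950, 1100), fs)
  expect_true(mix[["Exon"]] && mix[["3UTR"]] && mix[["Downstream"]])
  expect_false(mix[["Upstream"]] || mix[["5UTR"]] || mix[["Intron"]])
})

test_that("warning flags mark flank-only peaks and multi-expressed overlap", {
  flags_flank <- c(Upstream = TRUE, "5UTR" = FALSE, Exon = FALSE,
                   Intron = FALSE, "3UTR" = FALSE, Downstream = FALSE)
  flags_exon <- c(Upstream = FALSE, "5UTR" = FALSE, Exon = TRUE,
                  Intron = FALSE, "3UTR" = FALSE, Downstream = FALSE)
  expect_true(warn_flag(flags_flank, 1))
  expect_false(warn_flag(flags_exon, 1))
  expect_true(warn_flag(flags_exon, 2))   # two expressed genes overlap
})

test_that("annotate handles empty and all-intergenic inputs", {
  fx <- generate_fixture(fixture_spec(seed = 9))
  empty <- fx$peaks[0, ]
  ann <- annotate_peaks(empty, fx, fx$expression)
  expect_equal(nrow(ann$records), 0)
  expect_equal(nrow(ann$intergenic), 0)

  fx_int <- generate_fixture(fixture_spec(
    peak_classes = c(intergenic = 40), seed = 13))
  ann <- annotate_peaks(fx_int$peaks, fx_int, fx_int$expression)
  expect_equal(nrow(ann$records), 0)
  expect_equal(ann$intergenic$name, fx_int$peaks$name)
})

test_that("annotation matches recorded fixture truth on all placement classes", {
  fx <- generate_fixture(fixture_spec(seed = 2))
  ann <- annotate_peaks(fx$peaks, fx, fx$expression,
                        up_size = fx$spec$up_size,
                        down_size = fx$spec$down_size,
                        expression_threshold = fx$spec$expression_threshold)
  sc <- score_against_truth(ann, fx$truth)
  expect_equal(sc$correct_fraction, 1.0)
  expect_equal(sc$warning_fraction, 1.0)
  # every genic record carries at least one feature flag
  flag_mat <- as.matrix(ann$records[, c("Upstream", "5UTR", "Exon",
                                        "Intron", "3UTR", "Downstream")])
  expect_true(all(rowSums(flag_mat) >= 1))
})

test_that("expression split partitions the records in input order", {
  fx <- generate_fixture(fixture_spec(seed = 4))
  ann <- annotate_peaks(fx$peaks, fx, fx$expression)
  parts <- split_tables(ann)
  expect_equal(nrow(parts$expressed) + nrow(parts$unexpressed),
               nrow(parts$merged))
  expect_equal(parts$merged$peak, ann$records$peak)
  expect_true(all(parts$expressed$expressed))
  expect_false(any(parts$unexpressed$expressed))

  # without expression data everything lands in unexpressed
  ann0 <- annotate_peaks(fx$peaks, fx, NULL)
  parts0 <- split_tables(ann0)
  expect_equal(nrow(parts0$expressed), 0)
  expect_equal(nrow(parts0$unexpressed), nrow(ann0$records))
  expect_true(all(ann0$records$reason %in% c("single_gene", "largest_overlap")))
})

test_that("assignments are invariant under monotone expression transforms", {
  fx <- generate_fixture(fixture_spec(seed = 8))
  ann <- annotate_peaks(fx$peaks, fx, fx$expression)
  for (f in list(function(x) 5 * x^2, function(x) log1p(x) * 1000)) {
    ann2 <- annotate_peaks(fx$peaks, fx, f(fx$expression))
    expect_equal(ann2$records$gene, ann$records$gene)
    expect_equal(ann2$records$template_strand, ann$records$template_strand)
    expect_equal(ann2$records$reason, ann$records$reason)
    expect_equal(ann2$records$expressed, ann$records$expressed)
  }
})

test_that("raising a rival gene's expression above all others wins it the peak", {
  fx <- generate_fixture(fixture_spec(seed = 6))
  ann <- annotate_peaks(fx$peaks, fx, fx$expression)
  multi <- ann$records[nzchar(ann$records$rivals), ]
  expect_gt(nrow(multi), 0)
  r <- multi[1, ]
  rival <- strsplit(r$rivals, ",")[[1]][1]
  expr2 <- fx$expression
  expr2[rival] <- max(expr2) + 1
  ann2 <- annotate_peaks(fx$peaks, fx, expr2)
  expect_equal(ann2$records$gene[ann2$records$peak == r$peak], rival)
})

test_that("two runs on identical inputs produce byte-identical tables", {
  fx <- generate_fixture(fixture_spec(seed = 12))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(annotate_peaks(fx$peaks, fx, fx$expression)$records, f1)
  write_annotation_table(annotate_peaks(fx$peaks, fx, fx$expression)$records, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
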