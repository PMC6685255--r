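test_that("read_bed maps fields, auto-names, and skips decoration lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=demo",
               "# a comment",
               "chr1\t100\t500\tpk1",
               "browser position chr1",
               "",
               "chr2\t0\t10"), f)
  x <- read_bed(f)
  expect_equal(nrow(x), 2)
  expect_equal(x$name, c("pk1", "peak_6"))  # 3-column line auto-named by file line
  expect_equal(x$start, c(100, 0))
  expect_equal(x$end, c(500, 10))
})

test_that("read_bed rejects malformed lines with the line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t500", "chr1\t500\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t1.5\t500"), f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1\t100"), f)
  expect_error(read_bed(f), "3 columns")
})

test_that("read_bed12 parses blocks and enforces record consistency", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t1000\tgene1\t0\t+\t200\t800\t0\t2\t200,300,\t0,600,", f)
  g <- read_bed12(f)
  expect_equal(g$block_sizes[[1]], c(200, 300))
  expect_equal(g$block_starts[[1]], c(0, 600))

  writeLines("chr1\t100\t1000\tbad\t0\t+\t200\t800\t0\t2\t200,300,100,\t0,600,", f)
  expect_error(read_bed12(f), "bad")
  writeLines("chr1\t100\t1000\tdot\t0\t.\t200\t800\t0\t1\t900,\t0,", f)
  expect_error(read_bed12(f), "strand")
  writeLines("chr1\t100\t1000\tshort\t0\t+\t200\t800\t0\t2\t200,200,\t0,600,", f)
  expect_error(read_bed12(f), "chromEnd")
})

test_that("expression table handles headers, duplicates and bad values", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ttpm", "GeneA\t10.5", "GeneB\t0"), f)
  e <- read_expression_table(f)
  expect_equal(e, c(GeneA = 10.5, GeneB = 0))

  writeLines(c("GeneA 3", "GeneA 7", "GeneB 1"), f)
  expect_warning(e2 <- read_expression_table(f), "duplicate")
  expect_equal(e2[["GeneA"]], 7)  # maximum wins

  writeLines(c("GeneA\t-1"), f)
  expect_error(read_expression_table(f), "negative")
  writeLines(c("GeneA\t5", "GeneB\tten"), f)
  expect_error(read_expression_table(f), "non-numeric")

  expect_length(read_expression_table(NULL), 0)
})

test_that("BED write/read round-trips intervals exactly", {
  set.seed(77)
  x <- random_peaks(200)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(y[, c("chrom", "start", "end", "name")],
               x[, c("chrom", "start", "end", "name")])
})

test_that("annotation table layout is the documented 14 columns", {
  fx <- generate_fixture(fixture_spec(seed = 3))
  ann <- annotate_peaks(fx$peaks, fx, fx$expression)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_table(ann$records, f)
  tab <- read.table(f, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(names(tab),
               c("chrom", "start", "end", "peak", "gene", "strand",
                 "expression", "Upstream", "5UTR", "Exon", "Intron", "3UTR",
                 "Downstream", "warning"))
  expect_equal(nrow(tab), nrow(ann$records))
  expect_true(all(unlist(tab[, 8:14]) %in% 0:1))

  # empty record set still yields a header-only file
  write_annotation_table(ann$records[0, ], f)
  expect_equal(nrow(read.table(f, sep = "\t", header = TRUE,
                               check.names = FALSE)), 0)
})

test_that("every file the fixture generator writes parses cleanly", {
  d <- withr::local_tempdir()
  fx <- generate_fixture(fixture_spec(seed = 11), dir = d)
  peaks <- read_bed(file.path(d, "peaks.bed"))
  genes <- read_bed12(file.path(d, "genes.bed12"))
  expr <- read_expression_table(file.path(d, "expression.tsv"))
  sizes <- read_chrom_sizes(file.path(d, "chrom.sizes"))
  expect_equal(nrow(peaks), nrow(fx$peaks))
  expect_equal(nrow(genes), nrow(fx$genes))
  expect_equal(genes$block_sizes, fx$genes$block_sizes)
  expect_equal(sort(names(expr)), sort(names(fx$expression)))
  expect_equal(sizes, fx$chrom_sizes)
  # and the folder doubles as a loadable reference set
  ref <- load_reference(d)
  expect_equal(nrow(ref$genes), nrow(fx$genes))
})

test_that("chromosome mismatches are reported, not silently dropped", {
  fx <- generate_fixture(fixture_spec(seed = 5))
  pk <- fx$peaks
  pk$chrom[1] <- "chrX"
  ann <- annotate_peaks(pk, fx, fx$expression)
  expect_equal(ann$mismatch, "chrX")
  expect_true(pk$name[1] %in% ann$intergenic$name)
})
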