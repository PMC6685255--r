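test_that("feature decomposition of a two-exon coding gene", {
  fs <- derive_features(two_exon_gene("+"))
  expect_equal(interval_set(fs$exons), c("chr1:100:300", "chr1:700:1000"))
  expect_equal(interval_set(fs$introns), "chr1:300:700")
  expect_equal(interval_set(fs$utr5), "chr1:100:200")
  expect_equal(interval_set(fs$utr3), "chr1:800:1000")
  expect_equal(nrow(fs$upstream), 0)

  # same gene on the minus strand: UTRs swap, exons/introns unchanged
  fsm <- derive_features(two_exon_gene("-"))
  expect_equal(interval_set(fsm$utr5), "chr1:800:1000")
  expect_equal(interval_set(fsm$utr3), "chr1:100:200")
  expect_equal(interval_set(fsm$exons), interval_set(fs$exons))
  expect_equal(interval_set(fsm$introns), interval_set(fs$introns))
})

test_that("non-coding single-block gene has no UTRs and no introns", {
  g <- data.frame(chrom = "chr1", start = 50, end = 150, name = "nc",
                  score = 0, strand = "+", thick_start = 50, thick_end = 50,
                  block_count = 1, stringsAsFactors = FALSE)
  g$block_sizes <- list(100)
  g$block_starts <- list(0)
  fs <- derive_features(g)
  expect_equal(interval_set(fs$exons), "chr1:50:150")
  expect_equal(nrow(fs$introns), 0)
  expect_equal(nrow(fs$utr5), 0)
  expect_equal(nrow(fs$utr3), 0)
})

test_that("CDS covering the whole span leaves UTRs empty", {
  g <- random_genes(1)  # thick == span by construction
  fs <- derive_features(g)
  expect_equal(nrow(fs$utr5) + nrow(fs$utr3), 0)
})

test_that("flank regions are strand-aware and clamped", {
  g <- random_genes(1)
  g$start <- 5000; g$end <- 8000; g$thick_start <- 5000; g$thick_end <- 8000
  g$block_sizes <- list(3000)
  g$strand <- "+"
  fl <- flank_regions(g, 5000, 5000, chrom_len = 1e6)
  expect_equal(c(fl$upstream$start, fl$upstream$end), c(0, 5000))
  expect_equal(c(fl$downstream$start, fl$downstream$end), c(8000, 13000))
  g$strand <- "-"
  fl <- flank_regions(g, 5000, 5000, chrom_len = 1e6)
  expect_equal(c(fl$upstream$start, fl$upstream$end), c(8000, 13000))
  expect_equal(c(fl$downstream$start, fl$downstream$end), c(0, 5000))
  fl0 <- flank_regions(g, 0, 0, chrom_len = 1e6)
  expect_equal(nrow(fl0$upstream), 0)
  expect_equal(nrow(fl0$downstream), 0)
})

test_that("feature partition, UTR containment and strand involution hold on random gene models", {
  set.seed(421)
  for (i in 1:1000) {
    g <- random_gene_model()
    fs <- derive_features(g)
    span <- g$end - g$start
    ex_len <- sum(fs$exons$end - fs$exons$start)
    in_len <- sum(fs$introns$end - fs$introns$start)
    expect_equal(ex_len + in_len, span)
    # every UTR base must lie inside an exon block
    for (utr in list(fs$utr5, fs$utr3)) {
      if (nrow(utr) == 0) next
      inside <- vapply(seq_len(nrow(utr)), function(j)
        any(fs$exons$start <= utr$start[j] & fs$exons$end >= utr$end[j]),
        TRUE)
      expect_true(all(inside))
    }
    # flipping strand swaps the UTRs and leaves exons/introns unchanged
    gf <- g
    gf$strand <- if (g$strand == "+") "-" else "+"
    ff <- derive_features(gf)
    expect_equal(interval_set(ff$utr5), interval_set(fs$utr3))
    expect_equal(interval_set(ff$utr3), interval_set(fs$utr5))
    expect_equal(interval_set(ff$exons), interval_set(fs$exons))
    expect_equal(interval_set(ff$introns), interval_set(fs$introns))
    # and swaps the flanks
    fl <- flank_regions(g, 1000, 2000, 1e6)
    flf <- flank_regions(gf, 1000, 2000, 1e6)
    expect_equal(interval_set(flank_regions(g, 1000, 1000, 1e6)$upstream),
                 interval_set(flank_regions(gf, 1000, 1000, 1e6)$downstream))
  }
})

test_that("invalid gene models are rejected with the gene named", {
  g <- two_exon_gene()
  g$block_starts <- list(c(0, 100))  # second block overlaps the first
  expect_error(derive_features(g), "gene1")
  g2 <- two_exon_gene()
  g2$thick_end <- 2000
  expect_error(derive_features(g2), "thick")
})
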