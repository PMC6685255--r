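# Independent brute-force oracle and random-instance generators for
# property tests. Deliberately naive: all-pairs scans and direct
# arithmetic, no interval index, no reuse of package internals.

# all-pairs overlap scan against flank-extended gene spans
oracle_overlaps <- function(peaks, genes, up, down, sizes) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    if (!peaks$chrom[i] %in% names(sizes)) next
    same <- which(genes$chrom == peaks$chrom[i])
    if (!length(same)) next
    len <- sizes[[peaks$chrom[i]]]
    plus <- genes$strand[same] == "+"
    s <- genes$start[same] - ifelse(plus, up, down)
    e <- genes$end[same] + ifelse(plus, down, up)
    s <- pmax(0, s)
    e <- pmax(pmin(e, len), genes$end[same])
    ov <- pmin(peaks$end[i], e) - pmax(peaks$start[i], s)
    hit <- which(ov >= 1)
    if (length(hit)) {
      body <- pmax(0, pmin(peaks$end[i], genes$end[same[hit]]) -
                        pmax(peaks$start[i], genes$start[same[hit]]))
      out[[length(out) + 1]] <- data.frame(peak = i, gene = same[hit],
                                           overlap_bp = ov[hit],
                                           body_overlap_bp = body)
    }
  }
  if (!length(out))
    return(data.frame(peak = integer(0), gene = integer(0),
                      overlap_bp = numeric(0), body_overlap_bp = numeric(0)))
  do.call(rbind, out)
}

# random single-block gene models (valid BED12 semantics)
random_genes <- function(n, chroms = c("chr1", "chr2"), chrom_len = 1e6,
                         len_range = c(500, 20000)) {
  len <- round(runif(n, len_range[1], len_range[2]))
  start <- floor(runif(n, 0, chrom_len - len))
  g <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                  start = start, end = start + len,
                  name = sprintf("g%04d", seq_len(n)), score = 0,
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  thick_start = start, thick_end = start + len,
                  block_count = 1, stringsAsFactors = FALSE)
  g$block_sizes <- as.list(len)
  g$block_starts <- rep(list(0), n)
  g
}

random_peaks <- function(n, chroms = c("chr1", "chr2"), chrom_len = 1e6,
                         len_range = c(100, 8000)) {
  len <- round(runif(n, len_range[1], len_range[2]))
  start <- floor(runif(n, 0, chrom_len - len))
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + len,
                    name = sprintf("p%05d", seq_len(n)))
}

# random multi-block gene model, built directly (independent of the
# package's fixture generator): k blocks with positive gaps, random thick
# region snapped into [start, end]
random_gene_model <- function(chrom = "chr1", max_blocks = 6) {
  k <- sample.int(max_blocks, 1)
  sizes <- sample(50:400, k, replace = TRUE)
  gaps <- if (k > 1) sample(30:300, k - 1, replace = TRUE) else integer(0)
  starts <- cumsum(c(0, sizes[-k] + gaps))
  start <- sample.int(100000, 1)
  end <- start + starts[k] + sizes[k]
  tt <- sort(sample(seq(start, end), 2))
  if (runif(1) < 0.2) tt <- c(start, start)  # non-coding
  g <- data.frame(chrom = chrom, start = start, end = end,
                  name = "rg", score = 0,
                  strand = sample(c("+", "-"), 1),
                  thick_start = tt[1], thick_end = tt[2],
                  block_count = k, stringsAsFactors = FALSE)
  g$block_sizes <- list(sizes)
  g$block_starts <- list(starts)
  g
}

interval_set <- function(tab) {
  if (nrow(tab) == 0) return(character(0))
  sort(paste(tab$chrom, tab$start, tab$end, sep = ":"))
}

hit_key <- function(hits)
  sort(paste(hits$peak, hits$gene, hits$overlap_bp, hits$body_overlap_bp,
             sep = "/"))

# canonical small two-exon coding gene used across feature tests:
# span chr1:[100,1000)+, blocks [100,300) and [700,1000), CDS [200,800)
two_exon_gene <- function(strand = "+") {
  g <- data.frame(chrom = "chr1", start = 100, end = 1000, name = "gene1",
                  score = 0, strand = strand, thick_start = 200,
                  thick_end = 800, block_count = 2, stringsAsFactors = FALSE)
  g$block_sizes <- list(c(200, 300))
  g$block_starts <- list(c(0, 600))
  g
}
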