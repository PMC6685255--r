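ALL_FEATURES <- c(FEATURE_NAMES, "Intergenic")

#' Shuffle peaks genome-wide
#'
#' Length-preserving random placement in the style of a genome-wide
#' BEDtools shuffle: each peak keeps its length, lands on a chromosome
#' drawn with probability proportional to chromosome length (among
#' chromosomes long enough to hold it), at a start uniform on
#' `[0, chrom_len - peak_len]`. Shuffled peaks may overlap each other;
#' no exclusion regions are applied.
#'
#' @param peaks interval `data.frame`.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param seed integer; the same seed reproduces the same placement
#'   bit-for-bit. `NULL` uses the current RNG state.
#' @return Interval `data.frame` with the same names and lengths as the
#'   input, new positions.
#' @export
shuffle_peaks <- function(peaks, chrom_sizes, seed = NULL) {
  stopifnot(length(chrom_sizes) > 0)
  lens <- peaks$end - peaks$start
  too_long <- which(lens > max(chrom_sizes))
  if (length(too_long))
    stop("peak '", peaks$name[too_long[1]],
         "' is longer than every chromosome", call. = FALSE)
  with_seed(seed, {
    n <- nrow(peaks)
    nc <- length(chrom_sizes)
    ci <- integer(n)
    fits_all <- lens <= min(chrom_sizes)
    if (any(fits_all))
      ci[fits_all] <- sample.int(nc, sum(fits_all), replace = TRUE,
                                 prob = chrom_sizes)
    for (i in which(!fits_all)) {   # peaks too long for some chromosome
      ok <- which(chrom_sizes >= lens[i])
      ci[i] <- ok[sample.int(length(ok), 1, prob = chrom_sizes[ok])]
    }
    # uniform integer start on [0, chrom_len - peak_len]
    room <- unname(chrom_sizes[ci]) - lens
    new_start <- pmin(floor(stats::runif(n) * (room + 1)), room)
    genomic_intervals(names(chrom_sizes)[ci], new_start, new_start + lens,
                      name = peaks$name, strand = peaks$strand)
  })
}

#' Count peaks overlapping each feature
#'
#' One peak can contribute to several features (multi-feature annotation),
#' so the counts need not sum to the number of peaks.
#'
#' @param records annotation record `data.frame`.
#' @param intergenic interval `data.frame` of intergenic peaks.
#' @return Named integer vector over `Upstream`, `5UTR`, `Exon`, `Intron`,
#'   `3UTR`, `Downstream`, `Intergenic`.
#' @export
count_features <- function(records, intergenic = NULL) {
  n_int <- if (is.null(intergenic)) 0L else nrow(intergenic)
  counts <- vapply(FEATURE_NAMES, function(f) sum(records[[f]]), 0L)
  c(counts, Intergenic = n_int)
}

#' Fold enrichment of observed over shuffled feature counts
#'
#' @param observed named counts from [count_features()] on the query peaks.
#' @param shuffled_counts list (>= 2 elements) of the same, one per shuffle
#'   replicate.
#' @return `data.frame` with one row per feature: `observed`, `rand_mean`,
#'   `rand_sd` (sample SD across replicates), `fold` = observed/rand_mean
#'   (`Inf` when the null never hits the feature but the query does; 1 when
#'   both are 0 — the no-signal convention).
#' @export
fold_enrichment <- function(observed, shuffled_counts) {
  stopifnot(length(shuffled_counts) >= 2)
  m <- do.call(rbind, lapply(shuffled_counts, function(x) x[ALL_FEATURES]))
  obs <- as.numeric(observed[ALL_FEATURES])
  rand_mean <- colMeans(m)
  rand_sd <- apply(m, 2, stats::sd)
  fold <- ifelse(rand_mean > 0, obs / rand_mean, ifelse(obs > 0, Inf, 1))
  data.frame(feature = ALL_FEATURES, observed = obs,
             rand_mean = unname(rand_mean), rand_sd = unname(rand_sd),
             fold = unname(fold), stringsAsFactors = FALSE)
}

#' Chi-squared contingency test for one feature
#'
#' Pearson chi-squared without continuity correction on the 2x2 table
#' `[[observed_in, observed_out], [round(rand_in), round(rand_out)]]`
#' (1 df), via the closed form `n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#' A zero marginal makes the table degenerate; by convention the p-value
#' is then 1.
#'
#' @param observed_in,observed_out query peaks overlapping / not
#'   overlapping the feature.
#' @param rand_in,rand_out mean shuffled counts (rounded to integers for
#'   the table).
#' @return List: `statistic`, `p_value`, `degenerate`.
#' @export
chi2_feature_test <- function(observed_in, observed_out, rand_in, rand_out) {
  a <- as.numeric(observed_in); b <- as.numeric(observed_out)
  cc <- round(as.numeric(rand_in)); d <- round(as.numeric(rand_out))
  n <- a + b + cc + d
  marg <- c(a + b, cc + d, a + cc, b + d)
  if (n <= 0 || any(marg == 0))
    return(list(statistic = 0, p_value = 1, degenerate = TRUE))
  stat <- n * (a * d - b * cc)^2 / prod(marg)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Per-feature enrichment of query peaks over a shuffle null
#'
#' Shuffles the query peaks `n_shuffles` times, annotates every replicate
#' with exactly the same reference, expression table and parameters as the
#' query (like compared with like), and reports per-feature fold
#' enrichment with the null dispersion and a chi-squared p-value.
#'
#' @param peaks interval `data.frame` of query peaks.
#' @param reference an `rloop_reference` or folder path.
#' @param expression optional expression table (vector, path or `NULL`).
#' @param n_shuffles number of shuffle replicates (>= 2; default 10).
#' @param seed integer seed; replicate `i` is shuffled with `seed + i`, so
#'   the whole analysis is reproducible bit-for-bit.
#' @param up_size,down_size,expression_threshold as in [annotate_peaks()].
#' @param keep_shuffles also return the shuffled interval tables.
#' @return Object of class `rloop_enrichment`: `table` — `data.frame` with
#'   `feature`, `observed`, `rand_mean`, `rand_sd`, `fold`, `chi2`,
#'   `p_value`, `degenerate`; plus `n_peaks`, `n_shuffles`, `seed`, and
#'   optionally `shuffles`.
#' @export
feature_enrichment <- function(peaks, reference, expression = NULL,
                               n_shuffles = 10, seed = NULL,
                               up_size = 5000, down_size = 5000,
                               expression_threshold = 0,
                               keep_shuffles = FALSE) {
  stopifnot(n_shuffles >= 2)
  if (is.character(reference)) reference <- load_reference(reference)
  if (is.character(peaks)) peaks <- read_bed(peaks)
  ann <- function(p) {
    a <- annotate_peaks(p, reference, expression, up_size, down_size,
                        expression_threshold)
    count_features(a$records, a$intergenic)
  }
  observed <- ann(peaks)
  base_seed <- if (is.null(seed)) NULL else seed %% 1000000000
  shuffles <- vector("list", n_shuffles)
  shuffled_counts <- vector("list", n_shuffles)
  for (i in seq_len(n_shuffles)) {
    s <- if (is.null(base_seed)) NULL else base_seed + i
    shuffles[[i]] <- shuffle_peaks(peaks, reference$chrom_sizes, seed = s)
    shuffled_counts[[i]] <- ann(shuffles[[i]])
  }
  tab <- fold_enrichment(observed, shuffled_counts)
  n <- nrow(peaks)
  tests <- lapply(seq_len(nrow(tab)), function(i)
    chi2_feature_test(tab$observed[i], n - tab$observed[i],
                      tab$rand_mean[i], n - tab$rand_mean[i]))
  tab$chi2 <- vapply(tests, `[[`, 0, "statistic")
  tab$p_value <- vapply(tests, `[[`, 0, "p_value")
  tab$degenerate <- vapply(tests, `[[`, TRUE, "degenerate")
  structure(list(table = tab, n_peaks = n, n_shuffles = n_shuffles,
                 seed = seed,
                 shuffles = if (keep_shuffles) shuffles else NULL),
            class = "rloop_enrichment")
}

#' @export
print.rloop_enrichment <- function(x, ...) {
  cat(sprintf("Feature enrichment over %d shuffles of %d peaks\n",
              x$n_shuffles, x$n_peaks))
  tab <- x$table
  tab$rand_mean <- round(tab$rand_mean, 2)
  tab$rand_sd <- round(tab$rand_sd, 2)
  tab$fold <- round(tab$fold, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab[, c("feature", "observed", "rand_mean", "rand_sd", "fold",
                "p_value")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.rloop_enrichment <- function(x, ...) {
  plot_enrichment_panel(x$table, ...)
  invisible(x)
}
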