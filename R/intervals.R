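#' Construct a genomic-interval table
#'
#' Intervals are the atom of all overlap arithmetic in this package. They
#' follow the BED convention throughout: 0-based, half-open `[start, end)`,
#' so a 100 bp interval starting at position 0 is `start = 0, end = 100`.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end numeric vectors of 0-based half-open coordinates,
#'   `0 <= start < end`.
#' @param name optional interval labels; defaults to `interval_<i>`.
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, one row per interval.
#' @examples
#' genomic_intervals("chr1", 100, 500, name = "pk1")
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, strand = NULL) {
  n <- length(chrom)
  if (is.null(name)) name <- if (n) paste0("interval_", seq_len(n)) else character(0)
  if (is.null(strand)) strand <- rep(".", n)
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  name = as.character(name),
                  strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, context = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x)))
    stop(context, " table must have chrom/start/end columns", call. = FALSE)
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(sprintf("%s %s: invalid coordinates (need 0 <= start < end)",
                 context, paste(head(bad, 5), collapse = ",")), call. = FALSE)
  if (any(!nzchar(x$chrom) | is.na(x$chrom)))
    stop(context, ": empty chromosome name", call. = FALSE)
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop(context, ": strand must be one of +, -, .", call. = FALSE)
  invisible(x)
}

#' Overlap length between two intervals
#'
#' @param a,b single-row interval data frames (or lists with `chrom`,
#'   `start`, `end`).
#' @return Overlap in base pairs: `max(0, min(end) - max(start))` when the
#'   chromosomes match, 0 otherwise. Half-open adjacency (`a$end == b$start`)
#'   counts as 0.
#' @examples
#' a <- genomic_intervals("chr1", 0, 100)
#' b <- genomic_intervals("chr1", 50, 150)
#' overlap_length(a, b)  # 50
#' @export
overlap_length <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) return(0)
  max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1]))
}

# vectorised span overlap, same chromosome assumed
.ov_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# seed helper: runs code under a temporary RNG state when seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
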