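#' Region set constructor
#'
#' A region set is a BED-style data frame of genomic intervals in 0-based
#' half-open coordinates with columns `chrom`, `start`, `end`, `name`,
#' `score`, `strand`.
#'
#' @param chrom Chromosome names.
#' @param start 0-based starts.
#' @param end Exclusive ends (`start < end`).
#' @param name,score,strand Optional BED columns.
#' @return A `data.frame` with the six BED columns, sorted by
#'   (`chrom`, `start`).
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), name = NULL, score = NULL,
                       strand = NULL) {
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  if (n && any(start >= end)) stop("region_set requires start < end")
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   name = if (is.null(name)) rep(".", n) else as.character(name),
                   score = if (is.null(score)) rep(0, n) else as.numeric(score),
                   strand = if (is.null(strand)) rep(".", n) else as.character(strand),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# 0-based half-open region data.frame -> GRanges (1-based closed internally)
regions_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_regions <- function(gr, name = NULL, score = NULL, strand = NULL) {
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             name = name, score = score, strand = strand)
}

#' Merge overlapping and book-ended regions
#'
#' @param df Region set.
#' @param min_gap Intervals separated by less than `min_gap` bp are merged;
#'   the default 0 merges overlapping and book-ended intervals only.
#' @return Merged, sorted region set.
#' @export
merge_regions <- function(df, min_gap = 0) {
  if (!nrow(df)) return(region_set())
  gr <- GenomicRanges::reduce(regions_to_granges(df),
                              min.gapwidth = min_gap + 1L)
  granges_to_regions(gr)
}

#' Fraction of intervals in one set overlapping another
#'
#' Counts each interval of `a` once if it overlaps any interval of `b` by at
#' least `min_bp` bases.
#'
#' @param a,b Region sets (0-based half-open).
#' @param min_bp Minimum overlap in bp.
#' @return List with `fraction`, `n_overlap` and `n_total`.
#' @export
region_overlap_fraction <- function(a, b, min_bp = 1) {
  if (!nrow(a)) return(list(fraction = NaN, n_overlap = 0L, n_total = 0L))
  if (!nrow(b)) return(list(fraction = 0, n_overlap = 0L, n_total = nrow(a)))
  # disjoint chromosome sets are a legitimate zero-overlap case
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(regions_to_granges(a),
                                 regions_to_granges(b),
                                 minoverlap = min_bp))
  n <- sum(hits > 0)
  list(fraction = n / nrow(a), n_overlap = as.integer(n),
       n_total = nrow(a))
}

# which CpG positions (1-based) fall inside 0-based half-open [start, end)
cpg_in_region <- function(pos, start, end) pos > start & pos <= end

# fast scalar-interval vs region-set overlap test (rejection sampling helper)
overlaps_any <- function(chrom, start, end, df) {
  if (!nrow(df)) return(FALSE)
  j <- df$chrom == chrom
  any(df$start[j] < end & df$end[j] > start)
}

# per-interval index of overlapping CpGs; returns list parallel to df rows
cpg_overlap_index <- function(df, chrom, pos) {
  gr_cpg <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(regions_to_granges(df), gr_cpg)
  split(S4Vectors::subjectHits(hits),
        factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(df))))
}
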