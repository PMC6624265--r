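#' Bin a methylome into fixed-width genomic bins
#'
#' Computes, per non-overlapping bin, the weighted methylation level
#' \eqn{\sum M / \sum (M + U)} over the CpGs falling in the bin (the
#' read-level mean; a per-CpG mean-of-fractions switch is provided).
#' Bins with fewer than `min_cpg` CpGs or less than `min_cov` total reads
#' are marked invalid.
#'
#' @param tab CpG call table.
#' @param bin_bp Bin width in bp.
#' @param min_cpg,min_cov Validity thresholds.
#' @param chrom_sizes Optional named vector; bins then tile each chromosome
#'   exactly. Without it, bins extend to the last observed CpG.
#' @param weighting `"coverage"` (default, read-weighted) or `"cpg"`
#'   (unweighted mean of per-CpG fractions).
#' @return Data frame `chrom`, `start`, `end` (0-based half-open), `n_cpg`,
#'   `cov`, `meth`, `valid`.
#' @export
bin_methylation <- function(tab, bin_bp, min_cpg = 1, min_cov = 1,
                            chrom_sizes = NULL,
                            weighting = c("coverage", "cpg")) {
  weighting <- match.arg(weighting)
  if (bin_bp <= 0) stop("bin_bp must be positive")
  chroms <- if (!is.null(chrom_sizes)) names(chrom_sizes)
            else unique(tab$chrom)
  bins <- do.call(rbind, lapply(chroms, function(ch) {
    last <- if (!is.null(chrom_sizes)) chrom_sizes[[ch]]
            else max(tab$pos[tab$chrom == ch], 0)
    if (last < 1) return(NULL)
    st <- seq(0L, last - 1L, by = bin_bp)
    data.frame(chrom = ch, start = as.integer(st),
               end = as.integer(pmin(st + bin_bp, last)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(bins))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(), cov = numeric(),
                      meth = numeric(), valid = logical()))
  key <- paste0(tab$chrom, ":", (tab$pos - 1L) %/% bin_bp)
  bkey <- paste0(bins$chrom, ":", bins$start %/% bin_bp)
  sum_by <- function(x) {
    s <- tapply(x, key, sum)
    out <- rep(0, nrow(bins))
    m <- match(names(s), bkey)
    out[m[!is.na(m)]] <- s[!is.na(m)]
    out
  }
  bins$n_cpg <- as.integer(sum_by(rep(1L, nrow(tab))))
  M <- sum_by(tab$count_M); U <- sum_by(tab$count_U)
  bins$cov <- M + U
  if (weighting == "coverage") {
    bins$meth <- ifelse(bins$cov > 0, M / bins$cov, NA_real_)
  } else {
    cov_i <- tab$count_M + tab$count_U
    fr <- ifelse(cov_i > 0, tab$count_M / cov_i, NA_real_)
    s <- sum_by(ifelse(is.na(fr), 0, fr))
    nn <- sum_by(as.numeric(!is.na(fr)))
    bins$meth <- ifelse(nn > 0, s / nn, NA_real_)
  }
  bins$valid <- bins$n_cpg >= min_cpg & bins$cov >= min_cov &
    !is.na(bins$meth)
  bins
}

#' Histogram of single-CpG methylation levels
#'
#' @param tab CpG call table.
#' @param n_bins Number of equal-width bins partitioning \[0, 1\].
#' @param min_cov CpGs with coverage below this are excluded.
#' @return Data frame `lower`, `upper`, `count`; counts sum to the number
#'   of included CpGs.
#' @export
methylation_histogram <- function(tab, n_bins = 20, min_cov = 1) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  cov <- tab$count_M + tab$count_U
  keep <- cov >= min_cov & cov > 0
  fr <- tab$count_M[keep] / cov[keep]
  br <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(fr, br, rightmost.closed = TRUE), 1L), n_bins)
  cnt <- tabulate(idx, nbins = n_bins)
  data.frame(lower = br[-length(br)], upper = br[-1], count = cnt)
}

#' Pearson correlation between two binned methylomes
#'
#' Computed over the jointly valid bins only.
#'
#' @param col_a,col_b Outputs of [bin_methylation()] on the same bin grid,
#'   or numeric vectors with `NA` marking invalid bins.
#' @return List with `r`, `r2` and `n` (bins used).
#' @export
pairwise_bin_correlation <- function(col_a, col_b) {
  val <- function(x) {
    if (is.data.frame(x)) ifelse(x$valid, x$meth, NA_real_) else as.numeric(x)
  }
  a <- val(col_a); b <- val(col_b)
  if (length(a) != length(b)) stop("bin columns differ in length")
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 3)
    stop("insufficient data: need >= 3 jointly valid bins, got ", sum(keep))
  r <- stats::cor(a[keep], b[keep])
  list(r = r, r2 = r^2, n = sum(keep))
}

#' PCA of binned methylomes
#'
#' Samples are observations, bins are variables. Only bins valid in every
#' sample enter; columns are mean-centred and factored by singular value
#' decomposition (no scaling).
#'
#' @param meth Bins x samples matrix of methylation levels.
#' @param valid Optional logical matrix of the same shape; `NA`s in `meth`
#'   also mark invalid cells.
#' @return List with `scores` (samples x components), `loadings`,
#'   `var_explained` (fractions summing to 1), `n_bins` and `degenerate`
#'   (`TRUE` when total variance is numerically zero).
#' @export
pca_samples <- function(meth, valid = NULL) {
  if (ncol(meth) < 2) stop("need >= 2 samples")
  ok <- !is.na(meth)
  if (!is.null(valid)) ok <- ok & valid
  keep <- rowSums(ok) == ncol(meth)
  if (!any(keep)) stop("insufficient data: no bin is valid in every sample")
  x <- t(meth[keep, , drop = FALSE])          # samples x bins
  x <- sweep(x, 2, colMeans(x))
  total_var <- sum(x^2)
  if (total_var < 1e-12)
    return(list(scores = matrix(0, nrow(x), 1,
                                dimnames = list(rownames(x), "PC1")),
                loadings = NULL, var_explained = NA_real_,
                n_bins = sum(keep), degenerate = TRUE))
  sv <- svd(x)
  k <- sum(sv$d > sv$d[1] * 1e-12)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  dimnames(scores) <- list(colnames(meth), paste0("PC", seq_len(k)))
  list(scores = scores,
       loadings = sv$v[, seq_len(k), drop = FALSE],
       var_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
       n_bins = sum(keep), degenerate = FALSE)
}

#' Bin a set of methylomes onto one grid
#'
#' Convenience wrapper applying [bin_methylation()] per sample and
#' assembling the bins x samples matrices [pca_samples()] consumes.
#'
#' @param tables Named list of CpG call tables.
#' @param bin_bp Bin width.
#' @param chrom_sizes Named chromosome sizes (required so all samples share
#'   a grid).
#' @param ... Passed to [bin_methylation()].
#' @return List with `bins`, `meth`, `valid`.
#' @export
bin_methylomes <- function(tables, bin_bp, chrom_sizes, ...) {
  cols <- lapply(tables, bin_methylation, bin_bp = bin_bp,
                 chrom_sizes = chrom_sizes, ...)
  bins <- cols[[1]][, c("chrom", "start", "end")]
  meth <- sapply(cols, function(x) ifelse(x$valid, x$meth, NA_real_))
  valid <- sapply(cols, `[[`, "valid")
  list(bins = bins, meth = meth, valid = valid)
}
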