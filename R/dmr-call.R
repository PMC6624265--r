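#' Stitch differentially methylated CpGs into candidate regions
#'
#' Maximal runs of DMCs whose successive positions lie within `max_gap` bp
#' of each other become candidate intervals `[first - 1, last)` in 0-based
#' half-open coordinates (so the interval width equals the 1-based
#' inclusive span `last - first + 1`).
#'
#' @param dmcs Output of [per_cpg_test()] / [per_cpg_test_technical()], or
#'   any data frame with `chrom`, `pos` and logical `is_dmc`.
#' @param max_gap Maximum distance (bp) between successive DMCs in a run.
#' @return Data frame `chrom`, `start`, `end`, `n_dmc`, sorted and
#'   non-overlapping.
#' @export
stitch_dmrs <- function(dmcs, max_gap = 50) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_dmc = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(dmcs)) return(empty)
  d <- dmcs[if ("is_dmc" %in% names(dmcs)) dmcs$is_dmc else TRUE, ,
            drop = FALSE]
  if (!nrow(d)) return(empty)
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  new_run <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                 diff(d$pos) > max_gap)
  run <- cumsum(new_run)
  out <- data.frame(
    chrom = tapply(d$chrom, run, `[`, 1),
    start = as.integer(tapply(d$pos, run, min) - 1L),
    end = as.integer(tapply(d$pos, run, max)),
    n_dmc = as.integer(tapply(d$pos, run, length)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Filter stitched candidates and classify them as hypo/hyper in PGCs
#'
#' Applies, in order: minimum DMC count, minimum span, exclusion of any
#' candidate overlapping a repeat interval by >= 1 bp, and exclusion of
#' candidates where more than `max_lowcov_frac` of the CpGs inside have
#' pooled within-group coverage below `low_cov_thresh` in either group.
#' Survivors are classified `hypo_in_PGC` when every replicate pair shows a
#' mean methylation difference (PGC minus soma, coverage-weighted over the
#' region's CpGs) of at most `-min_delta`, `hyper_in_PGC` when every
#' replicate shows at least `+min_delta`, and `unclassified` otherwise
#' (retained, flagged).
#'
#' @param candidates Output of [stitch_dmrs()].
#' @param pgc,soma Per-replicate CpG call tables (replicates paired by
#'   index for the per-replicate difference).
#' @param repeats Region set of repeat intervals.
#' @param min_dmc,min_span,low_cov_thresh,max_lowcov_frac,min_delta Filter
#'   and classification thresholds.
#' @return Data frame of DMR records: interval, `n_dmc`, `n_cpg_total`,
#'   `span`, per-replicate `delta_rep*`, `frac_lowcov`, `repeat_overlap`,
#'   `class`.
#' @export
filter_and_classify <- function(candidates, pgc, soma, repeats,
                                min_dmc = 5, min_span = 50,
                                low_cov_thresh = 5, max_lowcov_frac = 0.25,
                                min_delta = 0.1) {
  n_rep <- min(length(pgc), length(soma))
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_dmc = integer(),
                      n_cpg_total = integer(), span = integer(),
                      frac_lowcov = numeric(), repeat_overlap = logical(),
                      class = character(), stringsAsFactors = FALSE)
  for (r in seq_len(n_rep)) empty[[paste0("delta_rep", r)]] <- numeric()
  if (!nrow(candidates)) return(empty)

  keep <- candidates$n_dmc >= min_dmc &
    (candidates$end - candidates$start) >= min_span
  cand <- candidates[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  if (nrow(repeats)) {
    ov <- GenomicRanges::countOverlaps(regions_to_granges(cand),
                                       regions_to_granges(repeats)) > 0
    cand <- cand[!ov, , drop = FALSE]
  }
  if (!nrow(cand)) return(empty)

  key <- union_positions(pgc, soma)
  g1 <- group_matrices(pgc, key$chrom, key$pos)
  g2 <- group_matrices(soma, key$chrom, key$pos)
  idx <- cpg_overlap_index(cand, key$chrom, key$pos)

  rows <- lapply(seq_len(nrow(cand)), function(i) {
    ii <- idx[[i]]
    n_cpg <- length(ii)
    cov1 <- rowSums(g1$N[ii, , drop = FALSE])
    cov2 <- rowSums(g2$N[ii, , drop = FALSE])
    lowcov <- cov1 < low_cov_thresh | cov2 < low_cov_thresh
    frac_low <- if (n_cpg) mean(lowcov) else 1
    deltas <- vapply(seq_len(n_rep), function(r) {
      m1 <- sum(g1$M[ii, r]); n1 <- sum(g1$N[ii, r])
      m2 <- sum(g2$M[ii, r]); n2 <- sum(g2$N[ii, r])
      if (n1 == 0 || n2 == 0) return(NA_real_)
      m1 / n1 - m2 / n2
    }, numeric(1))
    cls <- if (all(!is.na(deltas)) && all(deltas <= -min_delta))
      "hypo_in_PGC"
    else if (all(!is.na(deltas)) && all(deltas >= min_delta))
      "hyper_in_PGC"
    else "unclassified"
    c(list(chrom = cand$chrom[i], start = cand$start[i], end = cand$end[i],
           n_dmc = cand$n_dmc[i], n_cpg_total = n_cpg,
           span = cand$end[i] - cand$start[i], frac_lowcov = frac_low,
           repeat_overlap = FALSE, class = cls),
      stats::setNames(as.list(deltas), paste0("delta_rep", seq_len(n_rep))))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[out$frac_lowcov <= max_lowcov_frac, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call DMRs between PGC and soma at one developmental stage
#'
#' Convenience wrapper running the per-CpG test (biological-replicate
#' beta-binomial Wald, or paired-and-intersected technical mode), stitching
#' DMCs within `max_gap` bp, then filtering and classifying.
#'
#' @inheritParams per_cpg_test
#' @inheritParams filter_and_classify
#' @param mode `"biological"` or `"technical"` (technical is the 4 hpf
#'   design with paired technical replicates).
#' @param max_gap Stitching gap in bp.
#' @return List with `dmcs` and `dmrs`.
#' @export
call_dmrs <- function(pgc, soma, repeats,
                      mode = c("biological", "technical"),
                      alpha_dmc = 1e-3, max_gap = 50, min_dmc = 5,
                      min_span = 50, low_cov_thresh = 5,
                      max_lowcov_frac = 0.25, min_delta = 0.1,
                      fdr_gate = FALSE) {
  mode <- match.arg(mode)
  dmcs <- if (mode == "technical")
    per_cpg_test_technical(pgc, soma, alpha_dmc = alpha_dmc)
  else per_cpg_test(pgc, soma, alpha_dmc = alpha_dmc, fdr_gate = fdr_gate)
  cand <- stitch_dmrs(dmcs, max_gap = max_gap)
  dmrs <- filter_and_classify(cand, pgc, soma, repeats, min_dmc = min_dmc,
                              min_span = min_span,
                              low_cov_thresh = low_cov_thresh,
                              max_lowcov_frac = max_lowcov_frac,
                              min_delta = min_delta)
  list(dmcs = dmcs, dmrs = dmrs)
}
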