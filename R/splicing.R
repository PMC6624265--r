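qual_levels <- c("N", "VLOW", "LOW", "OK", "SOUND")

#' Coverage-filter PSI events
#'
#' Retains events whose read-coverage quality code is at least `VLOW` in
#' all eight design samples (PGC and soma at 7 and 24 hpf, two replicates).
#'
#' @param psi_table List with `psi`, `qual`, `samples` (see
#'   [simulate_psi()] / [read_psi_tsv()]).
#' @param min_qual Minimum acceptable quality code.
#' @return Character vector of retained event ids.
#' @export
filter_psi_coverage <- function(psi_table, min_qual = "VLOW") {
  if (ncol(psi_table$psi) != 8)
    stop("expected exactly the 8 design samples, got ",
         ncol(psi_table$psi))
  rank_min <- match(min_qual, qual_levels)
  q <- matrix(match(psi_table$qual, qual_levels),
              nrow(psi_table$qual), ncol(psi_table$qual))
  rownames(psi_table$psi)[rowSums(q >= rank_min) == 8]
}

# sample columns of one (tissue, stage) cell, replicate-ordered
psi_cols <- function(samples, tissue, stage) {
  j <- which(samples$tissue == tissue & samples$stage == stage)
  j[order(samples$replicate[j])]
}

#' Differentially included exons for one comparison
#'
#' Replicate-paired delta-PSI (replicate i versus replicate i); an event is
#' differential when the mean |dPSI| reaches `min_avg_dpsi`, every paired
#' |dPSI| reaches `min_pair_dpsi`, and the paired dPSIs agree in sign.
#'
#' @param psi_table PSI table list.
#' @param comparison One of `"tissue@7"`, `"tissue@24"` (PGC vs soma at
#'   that stage) or `"dev@PGC"`, `"dev@soma"` (7 vs 24 hpf within tissue).
#' @param events Optional event universe (defaults to
#'   [filter_psi_coverage()]).
#' @param min_avg_dpsi,min_pair_dpsi Rule thresholds (PSI units).
#' @return Data frame `event_id`, `dpsi_rep1`, `dpsi_rep2`, `mean_dpsi`,
#'   `differential`.
#' @export
differential_exons <- function(psi_table,
                               comparison = c("tissue@7", "tissue@24",
                                              "dev@PGC", "dev@soma"),
                               events = NULL, min_avg_dpsi = 15,
                               min_pair_dpsi = 5) {
  comparison <- match.arg(comparison)
  if (is.null(events)) events <- filter_psi_coverage(psi_table)
  s <- psi_table$samples
  cols <- switch(comparison,
    "tissue@7" = list(a = psi_cols(s, "PGC", 7), b = psi_cols(s, "soma", 7)),
    "tissue@24" = list(a = psi_cols(s, "PGC", 24),
                       b = psi_cols(s, "soma", 24)),
    "dev@PGC" = list(a = psi_cols(s, "PGC", 7), b = psi_cols(s, "PGC", 24)),
    "dev@soma" = list(a = psi_cols(s, "soma", 7),
                      b = psi_cols(s, "soma", 24)))
  x <- psi_table$psi[events, cols$a, drop = FALSE] -
    psi_table$psi[events, cols$b, drop = FALSE]
  mean_d <- rowMeans(x)
  same_sign <- sign(x[, 1]) == sign(x[, 2]) & sign(x[, 1]) != 0
  diffr <- abs(mean_d) >= min_avg_dpsi &
    rowSums(abs(x) >= min_pair_dpsi) == ncol(x) & same_sign
  data.frame(event_id = events, dpsi_rep1 = x[, 1], dpsi_rep2 = x[, 2],
             mean_dpsi = mean_d, differential = diffr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap of developmentally regulated exons between tissues
#'
#' Cross-tabulates membership of the PGC-developmental and
#' soma-developmental exon sets over the covered-event universe and applies
#' the two-sided Fisher exact test.
#'
#' @param dev_pgc,dev_soma Character vectors of event ids (subsets of
#'   `universe`).
#' @param universe Covered event ids.
#' @return List with `overlap` (count), `table` (2x2) and `p`.
#' @export
developmental_overlap_test <- function(dev_pgc, dev_soma, universe) {
  if (!length(universe)) stop("empty universe")
  if (!all(dev_pgc %in% universe) || !all(dev_soma %in% universe))
    stop("developmental sets must be subsets of the universe")
  in_p <- universe %in% dev_pgc
  in_s <- universe %in% dev_soma
  tab <- matrix(c(sum(in_p & in_s), sum(in_p & !in_s),
                  sum(!in_p & in_s), sum(!in_p & !in_s)),
                2, 2, byrow = TRUE,
                dimnames = list(c("PGC_dev", "PGC_stable"),
                                c("soma_dev", "soma_stable")))
  list(overlap = tab[1, 1], table = tab, p = fisher_exact_2x2(tab)$p)
}

#' Tissue-specific marker exons
#'
#' Stage-level tissue dPSI is the replicate-mean PGC PSI minus the
#' replicate-mean soma PSI at 7 and at 24 hpf. A marker needs |dPSI| >=
#' `min_stage_dpsi` at each stage with the same sign, |mean| >
#' `min_avg_dpsi`, and a two-sample t-test of the four PGC versus the four
#' soma PSI values below `alpha`.
#'
#' @param psi_table PSI table list.
#' @param events Optional event universe (defaults to coverage-filtered).
#' @param min_stage_dpsi,min_avg_dpsi,alpha Rule thresholds.
#' @return Data frame `event_id`, `dpsi_7`, `dpsi_24`, `mean_dpsi`,
#'   `t_p`, `marker`.
#' @export
tissue_marker_exons <- function(psi_table, events = NULL,
                                min_stage_dpsi = 10, min_avg_dpsi = 15,
                                alpha = 0.05) {
  if (is.null(events)) events <- filter_psi_coverage(psi_table)
  s <- psi_table$samples
  pgc_cols <- which(s$tissue == "PGC")
  soma_cols <- which(s$tissue == "soma")
  d7 <- rowMeans(psi_table$psi[events, psi_cols(s, "PGC", 7),
                               drop = FALSE]) -
    rowMeans(psi_table$psi[events, psi_cols(s, "soma", 7), drop = FALSE])
  d24 <- rowMeans(psi_table$psi[events, psi_cols(s, "PGC", 24),
                                drop = FALSE]) -
    rowMeans(psi_table$psi[events, psi_cols(s, "soma", 24), drop = FALSE])
  mean_d <- (d7 + d24) / 2
  t_p <- vapply(events, function(e) {
    x <- psi_table$psi[e, pgc_cols]
    y <- psi_table$psi[e, soma_cols]
    if (stats::sd(c(x, y)) == 0) return(1)
    tryCatch(stats::t.test(x, y)$p.value, error = function(err) 1)
  }, numeric(1))
  marker <- abs(d7) >= min_stage_dpsi & abs(d24) >= min_stage_dpsi &
    sign(d7) == sign(d24) & abs(mean_d) > min_avg_dpsi & t_p < alpha
  data.frame(event_id = events, dpsi_7 = d7, dpsi_24 = d24,
             mean_dpsi = mean_d, t_p = t_p, marker = marker,
             stringsAsFactors = FALSE, row.names = NULL)
}
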