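# Wide per-replicate count matrices over the union of CpG positions.
# Absent positions get zero coverage.
group_matrices <- function(tables, key_chrom, key_pos) {
  key <- paste0(key_chrom, ":", key_pos)
  M <- N <- matrix(0, length(key), length(tables))
  for (j in seq_along(tables)) {
    t_j <- tables[[j]]
    m <- match(paste0(t_j$chrom, ":", t_j$pos), key)
    ok <- !is.na(m)
    M[m[ok], j] <- t_j$count_M[ok]
    N[m[ok], j] <- t_j$count_M[ok] + t_j$count_U[ok]
  }
  list(M = M, N = N)
}

union_positions <- function(...) {
  tabs <- unlist(list(...), recursive = FALSE)
  all <- unique(do.call(rbind, lapply(tabs, function(t) t[, c("chrom", "pos")])))
  all[order(all$chrom, all$pos), , drop = FALSE]
}

# Beta-binomial moment statistics for one group: pooled mean, variance of the
# pooled estimate with method-of-moments dispersion (floored), per-CpG.
bb_group_stats <- function(g, rho_floor = 1e-3) {
  Ntot <- rowSums(g$N)
  Mtot <- rowSums(g$M)
  ph <- ifelse(Ntot > 0, Mtot / Ntot, NA_real_)
  R <- rowSums(g$N > 0)
  pi_hat <- ifelse(g$N > 0, g$M / g$N, 0)
  S <- rowSums(g$N * (pi_hat - ifelse(is.na(ph), 0, ph))^2)
  pq <- pmax(ph * (1 - ph), 1e-8)
  den <- Ntot - R - (rowSums(g$N^2) - Ntot) / pmax(Ntot, 1)
  rho <- (S / pq - (R - 1)) / pmax(den, 1e-8)
  rho <- pmin(pmax(rho, rho_floor), 0.99)
  v <- ph * (1 - ph) * rowSums(g$N * (1 + (g$N - 1) * rho)) /
    pmax(Ntot, 1)^2
  list(mu = ph, var = v, n = Ntot)
}

#' Per-CpG differential methylation test (biological replicates)
#'
#' For each CpG covered in both groups, compares the pooled methylated
#' fractions with a beta-binomial Wald test: the group mean is
#' \eqn{\sum M / \sum(M+U)} over replicates, its variance follows a
#' beta-binomial with per-CpG dispersion estimated by the method of moments
#' across replicates (floored at `rho_floor`), and
#' \eqn{z = d / \sqrt{var_1 + var_2}} is referred to the standard normal
#' (two-sided). No smoothing across neighbouring CpGs is applied.
#'
#' @param pgc,soma Lists of CpG call tables, one per replicate.
#' @param alpha_dmc Significance threshold defining a differentially
#'   methylated CpG (DMC).
#' @param rho_floor Lower bound of the dispersion estimate.
#' @param fdr_gate If `TRUE`, the DMC call uses Benjamini-Hochberg adjusted
#'   p-values at `alpha_dmc` instead of raw p-values.
#' @return Data frame with `chrom`, `pos`, `mu_pgc`, `mu_soma`, `d`
#'   (PGC minus soma), `stat`, `p`, `is_dmc`, sorted by position.
#' @export
per_cpg_test <- function(pgc, soma, alpha_dmc = 1e-3, rho_floor = 1e-3,
                         fdr_gate = FALSE) {
  if (!length(pgc) || !length(soma))
    stop("need >= 1 replicate per group")
  key <- union_positions(pgc, soma)
  g1 <- group_matrices(pgc, key$chrom, key$pos)
  g2 <- group_matrices(soma, key$chrom, key$pos)
  both <- rowSums(g1$N) > 0 & rowSums(g2$N) > 0
  if (!any(both)) {
    warning("no CpG covered in both groups")
    return(data.frame(chrom = character(), pos = integer(),
                      mu_pgc = numeric(), mu_soma = numeric(), d = numeric(),
                      stat = numeric(), p = numeric(), is_dmc = logical()))
  }
  key <- key[both, , drop = FALSE]
  g1 <- list(M = g1$M[both, , drop = FALSE], N = g1$N[both, , drop = FALSE])
  g2 <- list(M = g2$M[both, , drop = FALSE], N = g2$N[both, , drop = FALSE])
  s1 <- bb_group_stats(g1, rho_floor)
  s2 <- bb_group_stats(g2, rho_floor)
  d <- s1$mu - s2$mu
  v <- s1$var + s2$var
  z <- ifelse(v > 0, d / sqrt(v), ifelse(d == 0, 0, sign(d) * Inf))
  p <- 2 * stats::pnorm(-abs(z))
  res <- data.frame(chrom = key$chrom, pos = key$pos, mu_pgc = s1$mu,
                    mu_soma = s2$mu, d = d, stat = z, p = p,
                    stringsAsFactors = FALSE)
  res$is_dmc <- if (fdr_gate) bh_adjust(res$p) < alpha_dmc
                else res$p < alpha_dmc
  res[order(res$chrom, res$pos), , drop = FALSE]
}

#' Per-CpG test for technical replicates (paired, intersected)
#'
#' At stages profiled with technical rather than biological replicates the
#' test runs separately on each replicate pair (single-replicate binomial
#' Wald; no between-replicate dispersion is estimable), and only CpGs
#' significant in every pair with the same sign of difference are reported
#' as DMCs. The reported difference is the mean over pairs and the
#' reported p-value is the least significant pair.
#'
#' @inheritParams per_cpg_test
#' @return Data frame as [per_cpg_test()]; rows restricted to CpGs covered
#'   in every replicate of both groups.
#' @export
per_cpg_test_technical <- function(pgc, soma, alpha_dmc = 1e-3) {
  if (length(pgc) != length(soma))
    stop("technical mode requires equal replicate counts paired by index (",
         length(pgc), " vs ", length(soma), ")")
  key <- union_positions(pgc, soma)
  g1 <- group_matrices(pgc, key$chrom, key$pos)
  g2 <- group_matrices(soma, key$chrom, key$pos)
  keep <- rowSums(g1$N > 0) == length(pgc) & rowSums(g2$N > 0) == length(soma)
  key <- key[keep, , drop = FALSE]
  p1 <- g1$M[keep, , drop = FALSE] / g1$N[keep, , drop = FALSE]
  p2 <- g2$M[keep, , drop = FALSE] / g2$N[keep, , drop = FALSE]
  d <- p1 - p2
  v <- p1 * (1 - p1) / g1$N[keep, , drop = FALSE] +
    p2 * (1 - p2) / g2$N[keep, , drop = FALSE]
  z <- ifelse(v > 0, d / sqrt(v), ifelse(d == 0, 0, sign(d) * Inf))
  pv <- 2 * stats::pnorm(-abs(z))
  sig <- pv < alpha_dmc
  same_sign <- apply(sign(d), 1, function(s) all(s == s[1]) && all(s != 0))
  is_dmc <- rowSums(sig) == ncol(sig) & same_sign
  res <- data.frame(chrom = key$chrom, pos = key$pos,
                    mu_pgc = rowMeans(p1), mu_soma = rowMeans(p2),
                    d = rowMeans(d),
                    stat = apply(z, 1, function(x) x[which.min(abs(x))]),
                    p = apply(pv, 1, max), is_dmc = is_dmc,
                    stringsAsFactors = FALSE)
  res[order(res$chrom, res$pos), , drop = FALSE]
}
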