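#' Log-CPM normalisation
#'
#' Counts per million scaled by library size (column sums), then
#' `log(CPM + 1)` (natural log by default; base-2 switch provided).
#'
#' @param counts Gene x sample count matrix.
#' @param base Logarithm base (`exp(1)` or `2`).
#' @return Matrix of log(CPM + 1) values.
#' @export
normalize_log_cpm <- function(counts, base = exp(1)) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(colnames(counts)[lib <= 0], collapse = ", "))
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  log(cpm + 1, base = base)
}

# Per-gene negative-binomial dispersion by the method of moments on
# library-size-adjusted counts, moderated toward the common (median)
# dispersion across genes.
estimate_dispersion <- function(counts, groups, prior_df = 20) {
  lib <- colSums(counts)
  adj <- sweep(counts, 2, mean(lib) / lib, "*")
  disp_raw <- disp_signed <- df <- rep(0, nrow(counts))
  for (g in unique(groups)) {
    j <- which(groups == g)
    if (length(j) < 2) next
    m <- rowMeans(adj[, j, drop = FALSE])
    v <- apply(adj[, j, drop = FALSE], 1, stats::var)
    d <- ifelse(m > 0, (v - m) / m^2, 0)
    disp_signed <- disp_signed + d * (length(j) - 1)
    disp_raw <- disp_raw + pmax(d, 0) * (length(j) - 1)
    df <- df + (length(j) - 1)
  }
  disp_raw <- ifelse(df > 0, disp_raw / df, 0)
  # common dispersion from the *unfloored* moment estimates: the per-gene
  # estimator is right-skewed, so medians or trimmed means are biased low
  # at 2 replicates; the plain mean is unbiased to first order, with a
  # second-order correction for the random denominator
  usable <- df > 0 & rowMeans(adj) >= 5
  disp_common <- if (any(usable)) {
    d0 <- max(0, mean(disp_signed[usable] / df[usable]))
    d0 * (1 + d0 / 2)
  } else 0
  (prior_df * disp_common + df * disp_raw) / pmax(prior_df + df, 1)
}

# Exact conditional two-sided test of a balanced split of n into (a, n - a)
# under equal negative-binomial group sums with common dispersion:
# P(A = k | A + B = n) proportional to f(k) f(n - k), f = NB(mu = n/2,
# size = reps / disp); two-sided by the point-probability rule. disp = 0
# recovers the conditional binomial.
nb_split_test <- function(a, n, disp, reps = 2) {
  if (n == 0) return(1)
  k <- 0:n
  lp <- if (disp <= 0) stats::dbinom(k, n, 0.5, log = TRUE)
  else {
    size <- reps / disp
    stats::dnbinom(k, size = size, mu = n / 2, log = TRUE) +
      stats::dnbinom(n - k, size = size, mu = n / 2, log = TRUE)
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[a + 1] * (1 + 1e-7)]))
}

#' Differential expression between PGC and soma at one stage
#'
#' Self-contained exact test for small two-versus-two designs: per gene,
#' counts are adjusted to a common library size, pooled within group, and
#' the split of the pooled total between the groups is compared against
#' the balanced-split null with an exact conditional negative-binomial
#' test. The per-gene dispersion comes from a method-of-moments estimate
#' on the replicates, moderated toward the common dispersion across genes
#' (`prior_df` pseudo-replicates); dispersion zero recovers the exact
#' conditional binomial. Fold changes are `log2((CPM_A + c)/(CPM_B + c))`
#' with pseudocount `c` (CPM units).
#'
#' @param counts Gene x sample count matrix.
#' @param group_a,group_b Column names or indices of the two groups
#'   (A = PGC, B = soma by convention: positive log2FC means PGC-enriched).
#' @param pseudo_cpm Pseudocount in CPM units.
#' @param lfc_min,fdr_max Direction thresholds: `up` needs
#'   `log2FC > lfc_min` and `FDR < fdr_max`, `down` the mirror image.
#' @param prior_df Moderation weight of the common dispersion.
#' @return Data frame `gene`, `cpm_a`, `cpm_b`, `log2fc`, `p`, `fdr`
#'   (Benjamini-Hochberg within this call), `direction`.
#' @export
de_test <- function(counts, group_a, group_b, pseudo_cpm = 0.5,
                    lfc_min = 1.5, fdr_max = 0.05, prior_df = 20) {
  a_idx <- if (is.character(group_a)) match(group_a, colnames(counts))
           else group_a
  b_idx <- if (is.character(group_b)) match(group_b, colnames(counts))
           else group_b
  if (anyNA(a_idx) || anyNA(b_idx)) stop("unknown sample column(s)")
  if (length(a_idx) < 2 || length(b_idx) < 2)
    stop("need >= 2 replicates per group")
  sub <- counts[, c(a_idx, b_idx), drop = FALSE]
  groups <- rep(c("A", "B"), c(length(a_idx), length(b_idx)))
  lib <- colSums(sub)
  if (any(lib <= 0)) stop("zero library size")
  disp <- estimate_dispersion(sub, groups, prior_df)
  adj <- sweep(sub, 2, mean(lib) / lib, "*")
  a <- round(rowSums(adj[, groups == "A", drop = FALSE]))
  b <- round(rowSums(adj[, groups == "B", drop = FALSE]))
  n_reps <- min(sum(groups == "A"), sum(groups == "B"))
  p <- vapply(seq_along(a), function(i)
    nb_split_test(a[i], a[i] + b[i], disp[i], n_reps), numeric(1))
  p[a + b == 0] <- 1
  cpm_a <- rowMeans(sweep(sub[, groups == "A", drop = FALSE], 2,
                          lib[groups == "A"], "/")) * 1e6
  cpm_b <- rowMeans(sweep(sub[, groups == "B", drop = FALSE], 2,
                          lib[groups == "B"], "/")) * 1e6
  log2fc <- log2((cpm_a + pseudo_cpm) / (cpm_b + pseudo_cpm))
  fdr <- bh_adjust(p)
  direction <- ifelse(log2fc > lfc_min & fdr < fdr_max, "up",
                      ifelse(log2fc < -lfc_min & fdr < fdr_max, "down",
                             "ns"))
  data.frame(gene = rownames(counts), cpm_a = cpm_a, cpm_b = cpm_b,
             log2fc = log2fc, p = p, fdr = fdr, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stage-wise differential expression for the full design
#'
#' Runs [de_test()] PGC versus soma at each developmental stage.
#'
#' @param counts Gene x sample count matrix with `PGC_<stage>_r<rep>` /
#'   `soma_<stage>_r<rep>` columns.
#' @param stages Stages to test.
#' @param ... Passed to [de_test()].
#' @return Named list of per-stage [de_test()] results.
#' @export
de_all_stages <- function(counts, stages = c(4, 7, 24, 36), ...) {
  res <- lapply(stages, function(s) {
    a <- grep(paste0("^PGC_", s, "_r"), colnames(counts), value = TRUE)
    b <- grep(paste0("^soma_", s, "_r"), colnames(counts), value = TRUE)
    if (!length(a) || !length(b)) stop("missing samples for stage ", s)
    de_test(counts, a, b, ...)
  })
  names(res) <- as.character(stages)
  res
}

#' Consistent PGC markers: up at every stage
#'
#' @param de_results Named list of per-stage DE results covering all four
#'   stages.
#' @return Character vector of gene ids.
#' @export
call_consistent_markers <- function(de_results) {
  if (length(de_results) < 4)
    stop("need DE results for all four stages, got ",
         length(de_results))
  up <- lapply(de_results, function(d) d$gene[d$direction == "up"])
  sort(Reduce(intersect, up))
}

#' Consecutive-stage PGC regulators: up in >= 2 consecutive stages
#'
#' Stages are ordered 4, 7, 24, 36 hpf; a gene qualifies when it is
#' PGC-upregulated in at least two adjacent stages of that sequence.
#'
#' @param de_results Named list of per-stage DE results (names are stages).
#' @return Character vector of gene ids (a superset of the consistent
#'   markers).
#' @export
call_consecutive_regulators <- function(de_results) {
  stages <- as.character(c(4, 7, 24, 36))
  miss <- setdiff(stages, names(de_results))
  if (length(miss)) stop("missing stage(s): ", paste(miss, collapse = ", "))
  genes <- de_results[[1]]$gene
  up <- vapply(stages, function(s) {
    d <- de_results[[s]]
    genes %in% d$gene[d$direction == "up"]
  }, logical(length(genes)))
  up <- matrix(up, nrow = length(genes))
  consec <- rowSums(up[, 1:3, drop = FALSE] & up[, 2:4, drop = FALSE]) > 0
  sort(genes[consec])
}

#' Cluster regulator expression dynamics
#'
#' K-means on the z-scored per-stage log2 fold-change profiles, many
#' restarts under a fixed seed, with genes sorted canonically beforehand so
#' input order cannot change the result. Cluster labels are renumbered
#' 1..k by the mean stage of their peak fold change.
#'
#' @param genes Character vector of regulator gene ids.
#' @param de_results Named list of per-stage DE results.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart K-means restarts.
#' @return Data frame `gene`, `cluster`, plus the four `lfc_*` profile
#'   columns used.
#' @export
cluster_dynamics <- function(genes, de_results, k = 5, seed = 1L,
                             nstart = 50) {
  stages <- as.character(c(4, 7, 24, 36))
  genes <- sort(unique(genes))
  prof <- sapply(stages, function(s) {
    d <- de_results[[s]]
    d$log2fc[match(genes, d$gene)]
  })
  z <- t(apply(prof, 1, function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  k_max <- nrow(unique(z))
  if (k_max < k) {
    warning("fewer distinct profiles (", k_max, ") than clusters (", k,
            "); reducing k")
    k <- max(1, k_max)
  }
  set.seed(seed)
  km <- if (k == 1) list(cluster = rep(1L, length(genes)))
        else stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100)
  peak <- tapply(apply(prof, 1, which.max), km$cluster, mean)
  relabel <- match(seq_len(k), order(peak))
  data.frame(gene = genes, cluster = relabel[km$cluster],
             lfc_4 = prof[, 1], lfc_7 = prof[, 2], lfc_24 = prof[, 3],
             lfc_36 = prof[, 4], stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-species conservation of PGC enrichment
#'
#' For each foreign species panel (mean FPKM per sample, `PGC_*` and
#' `soma_*` columns), maps the regulators through the orthology table,
#' averages `log(FPKM + 1)` over the PGC and over the soma samples per
#' gene, and tests PGC versus soma with a paired t-test across genes. A
#' gene is conserved in a species when its PGC mean exceeds its soma mean;
#' the high-confidence set is conserved in every supplied species.
#'
#' @param genes Regulator gene ids (source species).
#' @param orthology Data frame `gene_id` plus one id column per species.
#' @param panels Named list of panels; names must match `species_cols`
#'   names.
#' @param species_cols Named character vector mapping panel name to the
#'   orthology column holding that species' gene ids.
#' @return List with `species` (per-species data frame of `t`, `p`,
#'   `n_genes`), `per_gene` (gene x species conservation flags) and
#'   `high_confidence` (character vector).
#' @export
conservation_test <- function(genes, orthology, panels,
                              species_cols = c(mouse = "mouse_gene",
                                               human = "human_gene")) {
  genes <- sort(unique(genes))
  flags <- matrix(NA, length(genes), length(panels),
                  dimnames = list(genes, names(panels)))
  stats_out <- data.frame(species = names(panels), t = NA_real_,
                          p = NA_real_, n_genes = 0L,
                          stringsAsFactors = FALSE)
  for (sp in names(panels)) {
    panel <- panels[[sp]]
    fid <- orthology[[species_cols[[sp]]]][match(genes, orthology$gene_id)]
    rows <- match(fid, panel$gene)
    ok <- !is.na(rows)
    if (!any(ok)) stop("no regulator maps into the ", sp, " panel")
    pgc_cols <- grep("^PGC_", names(panel), value = TRUE)
    soma_cols <- grep("^soma_", names(panel), value = TRUE)
    pgc <- rowMeans(log(panel[rows[ok], pgc_cols, drop = FALSE] + 1))
    soma <- rowMeans(log(panel[rows[ok], soma_cols, drop = FALSE] + 1))
    ht <- if (all(pgc == soma)) list(statistic = c(t = 0), p.value = 1)
          else stats::t.test(pgc, soma, paired = TRUE)
    i <- match(sp, stats_out$species)
    stats_out$t[i] <- unname(ht$statistic)
    stats_out$p[i] <- ht$p.value
    stats_out$n_genes[i] <- sum(ok)
    flags[ok, sp] <- pgc > soma
  }
  conserved_all <- rownames(flags)[rowSums(flags, na.rm = TRUE) ==
                                     length(panels) &
                                     rowSums(!is.na(flags)) == length(panels)]
  list(species = stats_out, per_gene = flags,
       high_confidence = sort(conserved_all))
}
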