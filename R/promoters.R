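#' Build the merged NMI set from peak files
#'
#' Concatenates non-methylated island (NMI) peak calls from several tissues
#' and merges overlapping and book-ended intervals into one island set.
#'
#' @param peak_files Character vector of BED paths, or a list of region-set
#'   data frames.
#' @return Merged, sorted region set.
#' @export
build_nmi_set <- function(peak_files) {
  if (!length(peak_files)) stop("need >= 1 peak file")
  sets <- lapply(peak_files, function(p)
    if (is.character(p)) read_bed(p) else p)
  merged <- merge_regions(do.call(rbind, lapply(sets, function(s)
    s[, c("chrom", "start", "end", "name", "score", "strand")])))
  merged$name <- sprintf("nmi_%04d", seq_len(nrow(merged)))
  merged
}

#' Link NMIs to transcription start sites
#'
#' NMIs overlapping at least one TSS by >= 1 bp (no flank) are retained as
#' promoter candidates with the overlapping gene ids attached; strand is
#' ignored for the overlap.
#'
#' @param nmis Merged NMI region set.
#' @param tss Region set of 1 bp TSS intervals with gene ids in `name`.
#' @return Data frame of candidates: NMI interval columns plus `gene_ids`
#'   (comma-separated) and `n_genes`.
#' @export
link_nmis_to_tss <- function(nmis, tss) {
  if (!nrow(nmis) || !nrow(tss))
    return(cbind(nmis[0, , drop = FALSE],
                 data.frame(gene_ids = character(), n_genes = integer())))
  hits <- GenomicRanges::findOverlaps(regions_to_granges(nmis),
                                      regions_to_granges(tss))
  q <- S4Vectors::queryHits(hits)
  genes <- tapply(tss$name[S4Vectors::subjectHits(hits)],
                  factor(q, levels = seq_len(nrow(nmis))),
                  function(g) paste(sort(unique(g)), collapse = ","))
  keep <- which(!is.na(genes))
  out <- nmis[keep, , drop = FALSE]
  out$gene_ids <- as.character(genes[keep])
  out$n_genes <- lengths(strsplit(out$gene_ids, ","))
  rownames(out) <- NULL
  out
}

#' Mean NMI methylation and pooled counts per sample
#'
#' Coverage-weighted mean 5mC per candidate NMI per sample, plus the pooled
#' methylated/unmethylated read counts retained for the Fisher test.
#' Candidates with zero covered CpGs in a sample get `NA` mean and zero
#' counts; candidates covered in no sample are flagged.
#'
#' @param candidates Output of [link_nmis_to_tss()].
#' @param tables Named list of CpG call tables (one per sample).
#' @return List with `candidates`, `meth` (candidates x samples), matrices
#'   `counts_M` / `counts_U`, and logical `uncovered`.
#' @export
nmi_methylation <- function(candidates, tables) {
  n <- nrow(candidates)
  samples <- names(tables)
  meth <- cM <- cU <- matrix(NA_real_, n, length(samples),
                             dimnames = list(candidates$name, samples))
  for (j in seq_along(tables)) {
    tab <- tables[[j]]
    idx <- cpg_overlap_index(candidates, tab$chrom, tab$pos)
    m <- vapply(idx, function(ii) sum(tab$count_M[ii]), numeric(1))
    u <- vapply(idx, function(ii) sum(tab$count_U[ii]), numeric(1))
    cM[, j] <- m; cU[, j] <- u
    meth[, j] <- ifelse(m + u > 0, m / (m + u), NA_real_)
  }
  uncovered <- rowSums(cM + cU, na.rm = TRUE) == 0
  list(candidates = candidates, meth = meth, counts_M = cM, counts_U = cU,
       uncovered = uncovered)
}

#' Screen promoter NMIs for developmental 5mC gain
#'
#' Evaluates the five gates defining a putative developmental 5mC target:
#' Pearson correlation of the replicate-averaged soma stage means with
#' developmental stage above `r_min`; 4 hpf methylation below `gate_4hpf`
#' in each replicate; 36 hpf methylation above `gate_36hpf` in each
#' replicate; adult brain and liver methylation above `gate_adult`.
#' Candidates failing gates are retained with their flags.
#'
#' @param nm Output of [nmi_methylation()]; columns must include the soma
#'   samples `soma_<stage>_r<rep>` for stages 4, 7, 24, 36 and the adult
#'   `brain_adult_r1` / `liver_adult_r1` samples.
#' @param r_min,gate_4hpf,gate_36hpf,gate_adult Gate thresholds.
#' @param stage_axis Correlate against stage rank (`"rank"`, default,
#'   invariant to the uneven 4/7/24/36 spacing) or hpf values (`"hpf"`).
#' @return Data frame: candidate columns plus per-gate flags, `pearson_r`
#'   and `gates_pass`.
#' @export
screen_candidates <- function(nm, r_min = 0.5, gate_4hpf = 0.025,
                              gate_36hpf = 0.15, gate_adult = 0.45,
                              stage_axis = c("rank", "hpf")) {
  stage_axis <- match.arg(stage_axis)
  stages <- c(4, 7, 24, 36)
  need <- c(outer(paste0("soma_", stages), paste0("_r", 1:2), paste0),
            "brain_adult_r1", "liver_adult_r1")
  miss <- setdiff(need, colnames(nm$meth))
  if (length(miss))
    stop("missing sample column(s): ", paste(miss, collapse = ", "))
  rep_cols <- lapply(1:2, function(r) paste0("soma_", stages, "_r", r))
  stage_mean <- vapply(seq_along(stages), function(si)
    rowMeans(nm$meth[, c(rep_cols[[1]][si], rep_cols[[2]][si]),
                     drop = FALSE]), numeric(nrow(nm$meth)))
  stage_mean <- matrix(stage_mean, nrow = nrow(nm$meth))
  axis <- if (stage_axis == "rank") seq_along(stages) else stages
  r <- apply(stage_mean, 1, function(m) {
    if (anyNA(m) || stats::sd(m) == 0) return(NA_real_)
    stats::cor(m, axis)
  })
  out <- nm$candidates
  out$pearson_r <- r
  out$gate_r <- !is.na(r) & r > r_min
  out$gate_4hpf <- nm$meth[, "soma_4_r1"] < gate_4hpf &
    nm$meth[, "soma_4_r2"] < gate_4hpf
  out$gate_36hpf <- nm$meth[, "soma_36_r1"] > gate_36hpf &
    nm$meth[, "soma_36_r2"] > gate_36hpf
  out$gate_brain <- nm$meth[, "brain_adult_r1"] > gate_adult
  out$gate_liver <- nm$meth[, "liver_adult_r1"] > gate_adult
  gate_cols <- c("gate_r", "gate_4hpf", "gate_36hpf", "gate_brain",
                 "gate_liver")
  for (g in gate_cols) out[[g]][is.na(out[[g]])] <- FALSE
  out$gates_pass <- Reduce(`&`, out[gate_cols])
  out$uncovered <- nm$uncovered
  out
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' Sums the probabilities of all 2x2 tables with the observed margins whose
#' point probability does not exceed that of the observed table (the
#' point-probability rule). Degenerate tables (any zero margin) return
#' p = 1 with a flag.
#'
#' @param tab 2x2 matrix or a length-4 vector `(a, b, c, d)` in row-major
#'   order.
#' @return List with `p`, `odds_ratio` and `degenerate`.
#' @export
fisher_exact_2x2 <- function(tab) {
  x <- round(as.numeric(tab))
  if (length(x) != 4 || any(x < 0) || anyNA(x))
    stop("need a 2x2 table of nonnegative counts")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(p = 1, odds_ratio = NaN, degenerate = TRUE))
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  supp <- lo:hi
  pr <- stats::dhyper(supp, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  or <- (a * d) / (b * c)
  list(p = p, odds_ratio = or, degenerate = FALSE)
}

#' Fisher test of early- versus late-stage NMI methylation
#'
#' For one candidate NMI and one replicate, pools the methylated and
#' unmethylated counts over the early stages (4 + 7 hpf) and the late
#' stages (24 + 36 hpf) into a 2x2 table and applies the two-sided Fisher
#' exact test.
#'
#' @param nm Output of [nmi_methylation()].
#' @param candidate Row index or candidate name.
#' @param replicate Replicate number (soma samples).
#' @return List with `p`, `table`, `degenerate`.
#' @export
fisher_stage_test <- function(nm, candidate, replicate) {
  i <- if (is.character(candidate))
    match(candidate, nm$candidates$name) else candidate
  if (is.na(i) || i < 1 || i > nrow(nm$candidates))
    stop("unknown candidate: ", candidate)
  early <- paste0("soma_", c(4, 7), "_r", replicate)
  late <- paste0("soma_", c(24, 36), "_r", replicate)
  miss <- setdiff(c(early, late), colnames(nm$counts_M))
  if (length(miss))
    stop("missing sample column(s): ", paste(miss, collapse = ", "))
  tab <- matrix(c(sum(nm$counts_M[i, early]), sum(nm$counts_U[i, early]),
                  sum(nm$counts_M[i, late]), sum(nm$counts_U[i, late])),
                2, 2, byrow = TRUE,
                dimnames = list(c("early", "late"), c("M", "U")))
  ft <- fisher_exact_2x2(tab)
  list(p = ft$p, table = tab, degenerate = ft$degenerate)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Independent step-up implementation: adjusted p-values are
#' `min(1, p * n / rank)` made monotone from the largest rank down, with
#' the original order restored.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and not be NA")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Finalise the promoter 5mC-target table
#'
#' Computes the per-replicate Fisher early-versus-late p-values for every
#' covered candidate, applies Benjamini-Hochberg correction within each
#' replicate (family = all tested NMIs), and reports two tiers: candidates
#' passing all screen gates, and the subset also significant
#' (`p.adj < padj_max` in both replicates), which carry `is_target = TRUE`.
#'
#' @param screened Output of [screen_candidates()].
#' @param nm The matching [nmi_methylation()] object.
#' @param padj_max Adjusted-p threshold.
#' @return `screened` extended with `fisher_p_rep1/2`, `padj_rep1/2`,
#'   `tier` (`"none"`, `"gated"`, `"significant"`) and `is_target`, sorted
#'   by the larger of the two adjusted p-values.
#' @export
finalize_targets <- function(screened, nm, padj_max = 0.01) {
  out <- screened
  if (!nrow(out)) {
    out$fisher_p_rep1 <- out$fisher_p_rep2 <- numeric()
    out$padj_rep1 <- out$padj_rep2 <- numeric()
    out$tier <- character(); out$is_target <- logical()
    return(out)
  }
  tested <- !screened$uncovered
  for (r in 1:2) {
    p <- rep(NA_real_, nrow(out))
    p[tested] <- vapply(which(tested), function(i)
      fisher_stage_test(nm, i, r)$p, numeric(1))
    out[[paste0("fisher_p_rep", r)]] <- p
    padj <- rep(NA_real_, nrow(out))
    padj[tested] <- bh_adjust(p[tested])
    out[[paste0("padj_rep", r)]] <- padj
  }
  sig <- !is.na(out$padj_rep1) & !is.na(out$padj_rep2) &
    out$padj_rep1 < padj_max & out$padj_rep2 < padj_max
  out$tier <- ifelse(out$gates_pass & sig, "significant",
                     ifelse(out$gates_pass, "gated", "none"))
  out$is_target <- out$tier == "significant"
  ord <- order(!out$is_target, pmax(out$padj_rep1, out$padj_rep2,
                                    na.rm = TRUE))
  out[ord, , drop = FALSE]
}

#' Project targets onto orthologous genes in a foreign species
#'
#' @param targets Target table from [finalize_targets()] (uses `gene_ids`).
#' @param orthology Data frame with the source gene column named `gene_id`
#'   and one column per foreign species.
#' @param foreign_meth Data frame keyed by foreign gene id (`gene` column)
#'   with one mean-5mC column per foreign sample.
#' @param species Column of `orthology` to map through.
#' @return List with `matrix` (target genes x foreign samples, `NA` when
#'   unmapped), `unmapped` (source gene ids without orthologue or without
#'   foreign data) and `one_to_many` (source ids mapping to several
#'   foreign ids).
#' @export
project_orthologues <- function(targets, orthology, foreign_meth,
                                species = "mouse_gene") {
  src <- unique(unlist(strsplit(targets$gene_ids, ",")))
  if (!length(src))
    return(list(matrix = matrix(numeric(), 0, 0), unmapped = character(),
                one_to_many = character()))
  omap <- orthology[orthology$gene_id %in% src, , drop = FALSE]
  n_map <- table(omap$gene_id)
  one_to_many <- names(n_map)[n_map > 1]
  vals <- foreign_meth[match(omap[[species]], foreign_meth$gene), ,
                       drop = FALSE]
  data_cols <- setdiff(names(foreign_meth), "gene")
  mat <- as.matrix(vals[, data_cols, drop = FALSE])
  rownames(mat) <- omap$gene_id
  mapped <- omap$gene_id[!is.na(vals$gene)]
  unmapped <- setdiff(src, mapped)
  mat <- mat[rownames(mat) %in% mapped, , drop = FALSE]
  list(matrix = mat, unmapped = sort(unmapped),
       one_to_many = sort(one_to_many))
}
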