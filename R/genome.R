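#' Build the genome model for a simulation
#'
#' Lays out chromosomes, CpG positions, gene TSSs, promoter non-methylated
#' islands (NMIs), repeat intervals and the planted feature classes described
#' by the configuration. CpGs are sparse in background sequence
#' (exponential spacing), dense inside NMIs and planted regions, mimicking
#' the CpG-island character of regulatory regions where developmental
#' methylation differences concentrate. Repeats never overlap NMIs or
#' planted regions, so the downstream repeat filter cannot remove truth.
#'
#' @param config A [sim_config()] object.
#' @return A `genome_model` list with elements `config`, `chrom_sizes`,
#'   `cpg` (data frame of 1-based CpG positions), `genes`, `regions`
#'   (region sets `repeats`, `nmis`, `tss`) and `truth` (the planted-feature
#'   ledger: `regions`, `genes`, `exons`).
#' @export
build_genome_model <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  sizes <- rep(config$genome_length %/% config$n_chrom, config$n_chrom)
  names(sizes) <- paste0("chr", seq_len(config$n_chrom))

  n_region <- with(config$n_planted, hypo4_dmr + hyper24_dmr + phylo_region)
  need_bp <- config$n_genes * 2000 + n_region * (max(config$dmr_width_range) + 2000) +
    config$repeat_fraction * config$genome_length
  if (need_bp > 0.9 * config$genome_length)
    stop("genome too small for requested features: need ~", round(need_bp),
         " bp of layout space but genome is ", config$genome_length,
         " bp; reduce n_genes, planted counts or repeat_fraction")

  ## gene TSSs on a jittered grid, proportionally per chromosome
  genes <- do.call(rbind, lapply(names(sizes), function(ch) {
    n_ch <- round(config$n_genes * sizes[[ch]] / sum(sizes))
    step <- sizes[[ch]] / (n_ch + 1)
    tss <- round(step * seq_len(n_ch) + stats::runif(n_ch, -step / 4, step / 4))
    tss <- pmin(pmax(tss, 3000L), sizes[[ch]] - 3000L)
    data.frame(chrom = ch, tss = as.integer(tss), stringsAsFactors = FALSE)
  }))
  genes <- genes[seq_len(min(nrow(genes), config$n_genes)), , drop = FALSE]
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)

  ## NMIs over a random subset of promoters
  nmi_genes <- sort(sample(nrow(genes), config$n_nmi_promoters))
  genes$has_nmi <- seq_len(nrow(genes)) %in% nmi_genes
  if (length(nmi_genes)) {
    w <- round(stats::runif(length(nmi_genes), config$nmi_width_range[1],
                            config$nmi_width_range[2]))
    off <- round(w * stats::runif(length(nmi_genes), 0.25, 0.75))
    st <- pmax(genes$tss[nmi_genes] - off, 0L)
    nmis <- region_set(genes$chrom[nmi_genes], st, st + w,
                       name = genes$gene_id[nmi_genes],
                       strand = genes$strand[nmi_genes])
  } else {
    nmis <- region_set()
  }

  ## planted regions, rejected against NMIs/each other with a 1 kb buffer
  classes <- rep(c("hypo4_dmr", "hyper24_dmr", "phylo_region"),
                 times = c(config$n_planted$hypo4_dmr,
                           config$n_planted$hyper24_dmr,
                           config$n_planted$phylo_region))
  occupied <- nmis
  planted <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    w <- round(stats::runif(1, config$dmr_width_range[1], config$dmr_width_range[2]))
    placed <- FALSE
    for (try in seq_len(5000)) {
      ch <- sample(names(sizes), 1, prob = sizes)
      st <- floor(stats::runif(1, 4000, sizes[[ch]] - 4000 - w))
      if (!overlaps_any(ch, st - 1000, st + w + 1000, occupied)) {
        cand <- region_set(ch, st, st + w)
        planted[[i]] <- cand
        occupied <- rbind(occupied, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place planted region ", i, " (", classes[i],
           "): genome too crowded; the binding constraint is the 1 kb ",
           "buffer around NMIs and previously planted regions")
  }
  if (length(classes)) {
    planted <- do.call(rbind, planted)
    planted$name <- sprintf("%s_%03d", classes,
                            stats::ave(seq_along(classes), classes, FUN = seq_along))
    planted$class <- classes
    planted <- planted[order(planted$chrom, planted$start), , drop = FALSE]
  } else {
    planted <- cbind(region_set(), data.frame(class = character()))
  }

  ## repeats: random intervals avoiding NMIs and planted regions (200 bp buffer)
  target_bp <- config$repeat_fraction * config$genome_length
  avoid <- rbind(occupied[, 1:6], region_set())
  reps <- list()
  got <- 0
  for (try in seq_len(50000)) {
    if (got >= target_bp) break
    w <- round(stats::runif(1, 200, 2000))
    ch <- sample(names(sizes), 1, prob = sizes)
    st <- floor(stats::runif(1, 0, sizes[[ch]] - w))
    if (!overlaps_any(ch, st - 200, st + w + 200, avoid)) {
      reps[[length(reps) + 1]] <- region_set(ch, st, st + w)
      got <- got + w
    }
  }
  if (got < target_bp)
    stop("could not reach repeat_fraction ", config$repeat_fraction,
         ": placed ", got, " of ", round(target_bp),
         " bp; the binding constraint is free space between NMIs and ",
         "planted regions")
  repeats <- merge_regions(do.call(rbind, reps))
  repeats$name <- sprintf("rep_%04d", seq_len(nrow(repeats)))

  ## CpG positions: sparse background + dense grids in NMIs and planted regions
  cpg <- do.call(rbind, lapply(names(sizes), function(ch) {
    n_exp <- ceiling(sizes[[ch]] / config$cpg_spacing_mean * 1.3)
    sp <- pmax(2, round(stats::rexp(n_exp, 1 / config$cpg_spacing_mean)))
    pos <- cumsum(sp)
    pos <- pos[pos < sizes[[ch]]]
    dense <- function(df, by) {
      df <- df[df$chrom == ch, , drop = FALSE]
      if (!nrow(df)) return(integer())
      unlist(lapply(seq_len(nrow(df)), function(i)
        seq(df$start[i] + 3L, df$end[i] - 1L, by = by)))
    }
    pos <- sort(unique(c(pos, dense(nmis, config$island_spacing),
                         dense(planted, config$dmr_spacing))))
    data.frame(chrom = ch, pos = as.integer(pos), stringsAsFactors = FALSE)
  }))

  if (nrow(planted)) {
    idx <- cpg_overlap_index(planted, cpg$chrom, cpg$pos)
    n_in <- lengths(idx)
    if (any(n_in < 8))
      stop("planted region(s) with fewer than 8 CpGs: ",
           paste(planted$name[n_in < 8], collapse = ", "))
  }

  ## expression / splicing truth: genes disjoint from promoter targets
  pt_idx <- if (config$n_planted$promoter_target)
    sort(sample(nmi_genes, config$n_planted$promoter_target)) else integer()
  pool <- setdiff(seq_len(nrow(genes)), pt_idx)
  n_mark <- config$n_planted$consistent_marker
  n_reg <- config$n_planted$consecutive_regulator
  if (length(pool) < n_mark + n_reg)
    stop("not enough genes for planted markers and regulators")
  pick <- sample(pool, n_mark + n_reg)
  marker_idx <- pick[seq_len(n_mark)]
  reg_idx <- pick[n_mark + seq_len(n_reg)]
  archetypes <- c("up_early", "up_mid", "up_late", "early_sustained",
                  "late_sustained")
  reg_arch <- archetypes[(seq_len(n_reg) - 1L) %% length(archetypes) + 1L]
  conserved <- rep(FALSE, n_reg)
  conserved[sample(n_reg, min(config$n_conserved, n_reg))] <- TRUE

  truth_genes <- rbind(
    if (n_mark) data.frame(gene_id = genes$gene_id[marker_idx],
                           class = "consistent_marker", archetype = "all_stages",
                           fold_change = config$marker_fc, conserved = FALSE,
                           stringsAsFactors = FALSE),
    if (n_reg) data.frame(gene_id = genes$gene_id[reg_idx],
                          class = "consecutive_regulator", archetype = reg_arch,
                          fold_change = round(stats::runif(n_reg,
                            config$regulator_fc_range[1],
                            config$regulator_fc_range[2]), 2),
                          conserved = conserved, stringsAsFactors = FALSE))
  if (is.null(truth_genes))
    truth_genes <- data.frame(gene_id = character(), class = character(),
                              archetype = character(), fold_change = numeric(),
                              conserved = logical(), stringsAsFactors = FALSE)

  n_ex <- config$n_planted$diff_exon
  truth_exons <- data.frame(
    event_id = sprintf("ex%04d", seq_len(n_ex)),
    gene_id = if (n_ex) genes$gene_id[sample(nrow(genes), n_ex, replace = TRUE)]
              else character(),
    type = rep(c("tissue", "stage"), length.out = n_ex),
    offset = if (n_ex) round(stats::runif(n_ex, config$psi_offset_range[1],
                                          config$psi_offset_range[2]) *
                             sample(c(-1, 1), n_ex, replace = TRUE), 1)
             else numeric(),
    stringsAsFactors = FALSE)

  truth_regions <- planted[, c("class", "chrom", "start", "end", "name")]
  if (length(pt_idx)) {
    pt <- nmis[match(genes$gene_id[pt_idx], nmis$name), , drop = FALSE]
    truth_regions <- rbind(truth_regions,
                           data.frame(class = "promoter_target",
                                      chrom = pt$chrom, start = pt$start,
                                      end = pt$end, name = pt$name,
                                      stringsAsFactors = FALSE))
  }
  rownames(truth_regions) <- NULL

  tss <- region_set(genes$chrom, genes$tss - 1L, genes$tss,
                    name = genes$gene_id, strand = genes$strand)

  model <- list(config = config, chrom_sizes = sizes, cpg = cpg,
                genes = genes,
                regions = list(repeats = repeats, nmis = nmis, tss = tss,
                               planted = planted),
                truth = list(regions = truth_regions, genes = truth_genes,
                             exons = truth_exons, seed = config$seed))
  class(model) <- "genome_model"
  model
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_sizes), "chromosomes (",
      sum(x$chrom_sizes), "bp ),", nrow(x$cpg), "CpGs\n")
  cat("  genes:", nrow(x$genes), " NMIs:", nrow(x$regions$nmis),
      " repeats:", nrow(x$regions$repeats), "\n")
  cat("  planted:", paste(names(table(x$truth$regions$class)),
                          table(x$truth$regions$class), collapse = ", "), "\n")
  invisible(x)
}
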