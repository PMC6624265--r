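#' Sample design of the methylome simulation
#'
#' Sixteen embryonic samples (PGC and soma at 4, 7, 24, 36 hpf, two
#' replicates each) plus single adult brain, liver, sperm and oocyte
#' methylomes. The 4 hpf replicates are labelled technical, later stages
#' biological; the DMR caller branches on this label.
#'
#' @return Data frame with columns `sample_id`, `tissue`, `stage`,
#'   `replicate`, `replicate_type`.
#' @export
methylome_sample_sheet <- function() {
  emb <- expand.grid(replicate = 1:2, stage = c(4, 7, 24, 36),
                     tissue = c("PGC", "soma"), stringsAsFactors = FALSE)
  emb <- emb[, c("tissue", "stage", "replicate")]
  emb$replicate_type <- ifelse(emb$stage == 4, "technical", "biological")
  adult <- data.frame(tissue = c("brain", "liver", "sperm", "oocyte"),
                      stage = "adult", replicate = 1L,
                      replicate_type = "biological",
                      stringsAsFactors = FALSE)
  emb$stage <- as.character(emb$stage)
  sheet <- rbind(emb, adult)
  sheet$sample_id <- paste0(sheet$tissue, "_", sheet$stage, "_r",
                            sheet$replicate)
  sheet[, c("sample_id", "tissue", "stage", "replicate", "replicate_type")]
}

# per-CpG methylation mean for one sample given the planted truth
methylation_mu <- function(model, tissue, stage) {
  cfg <- model$config
  mu <- rep(cfg$baseline_meth, nrow(model$cpg))
  stages <- c("4", "7", "24", "36")
  si <- match(stage, stages)  # NA for adults

  assign_mu <- function(df, value) {
    if (!nrow(df)) return()
    idx <- unlist(cpg_overlap_index(df, model$cpg$chrom, model$cpg$pos))
    mu[idx] <<- value
  }

  ## stable NMIs: unmethylated everywhere (embryo and adult)
  tr <- model$truth$regions
  pt_names <- tr$name[tr$class == "promoter_target"]
  nmis <- model$regions$nmis
  assign_mu(nmis[!nmis$name %in% pt_names, , drop = FALSE], 0.02)

  ## promoter targets: developmental 5mC gain, sperm stays naive
  pt <- tr[tr$class == "promoter_target", , drop = FALSE]
  pt_val <- if (!is.na(si)) c(0.01, 0.05, 0.20, 0.30)[si]
            else switch(tissue, brain = 0.60, liver = 0.60,
                        oocyte = 0.70, sperm = 0.02)
  assign_mu(pt, pt_val)

  hypo4 <- tr[tr$class == "hypo4_dmr", , drop = FALSE]
  hyper24 <- tr[tr$class == "hyper24_dmr", , drop = FALSE]
  phylo <- tr[tr$class == "phylo_region", , drop = FALSE]

  if (!is.na(si)) {
    assign_mu(hypo4, if (tissue == "PGC") c(0.3, 0.55, 0.8, 0.8)[si] else 0.8)
    assign_mu(hyper24, if (tissue == "PGC") c(0.8, 0.8, 0.6, 0.25)[si]
                       else c(0.8, 0.8, 0.2, 0.2)[si])
    assign_mu(phylo, if (tissue == "PGC") c(0.8, 0.8, 0.6, 0.4)[si]
                     else c(0.8, 0.6, 0.4, 0.2)[si])
  } else if (tissue == "sperm") {
    # the embryonic methylome is paternally inherited: sperm carries the
    # early-embryo state over the planted developmental regions
    assign_mu(hypo4, 0.8)
    assign_mu(hyper24, 0.8)
    assign_mu(phylo, 0.8)
  } else {
    # oocyte and differentiated adult soma carry the late/differentiated
    # state: developmental regions demethylated, island promoters gained
    assign_mu(hypo4, 0.8)
    assign_mu(hyper24, 0.2)
    assign_mu(phylo, 0.2)
  }
  mu
}

#' Simulate per-CpG methylomes for every sample
#'
#' Per CpG, read depth is negative binomial and the methylated count is
#' beta-binomial with overdispersion `bb_rho` around a mean determined by
#' the planted truth: background at `baseline_meth`, NMIs unmethylated,
#' planted DMR classes following their tissue/stage trajectories, and
#' promoter-target NMIs gaining methylation from 4 to 36 hpf in both
#' tissues while staying unmethylated in sperm and methylated in oocyte
#' and adult soma.
#'
#' @param model A [build_genome_model()] result.
#' @return List with `samples` (the sample sheet) and `tables`, a named list
#'   of per-sample CpG call tables (`chrom`, `pos`, `count_M`, `count_U`).
#' @export
simulate_methylomes <- function(model) {
  cfg <- model$config
  sheet <- methylome_sample_sheet()
  n_cpg <- nrow(model$cpg)
  tables <- vector("list", nrow(sheet))
  names(tables) <- sheet$sample_id
  set.seed(cfg$seed + 1L)
  for (i in seq_len(nrow(sheet))) {
    mu <- methylation_mu(model, sheet$tissue[i], sheet$stage[i])
    cov <- pmax(1L, stats::rnbinom(n_cpg, mu = cfg$coverage_mean,
                                   size = cfg$coverage_size))
    p <- stats::rbeta(n_cpg, mu * (1 - cfg$bb_rho) / cfg$bb_rho,
                      (1 - mu) * (1 - cfg$bb_rho) / cfg$bb_rho)
    m <- stats::rbinom(n_cpg, cov, p)
    tables[[i]] <- data.frame(chrom = model$cpg$chrom, pos = model$cpg$pos,
                              count_M = m, count_U = cov - m,
                              stringsAsFactors = FALSE)
  }
  list(samples = sheet, tables = tables)
}

# convenience: weighted methylation fraction of a table over given row index
pooled_fraction <- function(tab, idx = seq_len(nrow(tab))) {
  m <- sum(tab$count_M[idx]); u <- sum(tab$count_U[idx])
  if (m + u == 0) return(NA_real_)
  m / (m + u)
}
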