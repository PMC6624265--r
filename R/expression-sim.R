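#' Simulate RNA-seq counts and foreign-species expression panels
#'
#' Counts for the sixteen embryonic samples follow a negative binomial with
#' log-normal baseline means. Consistent markers are elevated `marker_fc`
#' fold in PGCs at every stage; consecutive regulators are elevated 4-6 fold
#' in the stages dictated by their archetype (up-early, up-mid, up-late,
#' early-sustained, late-sustained; none spans all four stages, so the
#' all-stage marker set stays distinct). Mean-FPKM panels for two foreign
#' species carry a planted conserved subset of regulators elevated in PGCs,
#' linked by a one-to-one orthology map.
#'
#' @param model A [build_genome_model()] result.
#' @return List with `counts` (gene x sample integer matrix), `samples`,
#'   `fpkm_panels` (named list of mean-FPKM data frames with `PGC_*` and
#'   `soma_*` columns), and `orthology` (columns `gene_id`, `mouse_gene`,
#'   `human_gene`).
#' @export
simulate_expression <- function(model) {
  cfg <- model$config
  set.seed(cfg$seed + 3L)
  sheet <- methylome_sample_sheet()
  sheet <- sheet[sheet$stage != "adult", , drop = FALSE]
  genes <- model$genes$gene_id
  n_g <- length(genes)

  base <- stats::rlnorm(n_g, cfg$expr_meanlog, cfg$expr_sdlog)
  names(base) <- genes
  planted <- model$truth$genes$gene_id
  base[planted] <- stats::rlnorm(length(planted), cfg$planted_meanlog,
                                 cfg$planted_sdlog)

  arch_stages <- list(up_early = c("4", "7"), up_mid = c("7", "24"),
                      up_late = c("24", "36"),
                      early_sustained = c("4", "7", "24"),
                      late_sustained = c("7", "24", "36"),
                      all_stages = c("4", "7", "24", "36"))
  tg <- model$truth$genes
  fc <- matrix(1, n_g, 4, dimnames = list(genes, c("4", "7", "24", "36")))
  for (i in seq_len(nrow(tg)))
    fc[tg$gene_id[i], arch_stages[[tg$archetype[i]]]] <- tg$fold_change[i]

  counts <- matrix(0L, n_g, nrow(sheet),
                   dimnames = list(genes, sheet$sample_id))
  size <- 1 / cfg$expr_dispersion
  for (j in seq_len(nrow(sheet))) {
    mu <- base * if (sheet$tissue[j] == "PGC") fc[, sheet$stage[j]] else 1
    counts[, j] <- stats::rnbinom(n_g, mu = mu, size = size)
  }

  ## orthology map over all planted marker/regulator genes (one-to-one)
  ortho <- data.frame(gene_id = tg$gene_id,
                      mouse_gene = paste0("mmu_", tg$gene_id),
                      human_gene = paste0("hsa_", tg$gene_id),
                      stringsAsFactors = FALSE)

  panel <- function(foreign_ids, conserved, n_stage) {
    b <- stats::rlnorm(length(foreign_ids), log(10), 1)
    cols <- c(paste0("PGC_s", seq_len(n_stage)),
              paste0("soma_s", seq_len(n_stage)))
    m <- sapply(cols, function(cn) {
      up <- startsWith(cn, "PGC")
      b * ifelse(conserved, if (up) 6 else 1, if (up) 0.8 else 1) *
        stats::runif(length(b), 0.9, 1.1)
    })
    df <- as.data.frame(m)
    df <- cbind(data.frame(gene = foreign_ids, stringsAsFactors = FALSE), df)
    df
  }
  cons <- tg$conserved
  panels <- list(mouse = panel(ortho$mouse_gene, cons, 4),
                 human = panel(ortho$human_gene, cons, 4))

  list(counts = counts, samples = sheet, fpkm_panels = panels,
       orthology = ortho)
}
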