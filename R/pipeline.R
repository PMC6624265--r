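#' Pipeline configuration with the study's threshold defaults
#'
#' Every analysis threshold is surfaced here with its standard default:
#' DMC p < 1e-3, 50 bp stitching gap, >= 5 DMCs, >= 50 bp span, 5x / 25%
#' low-coverage rule, 0.1 minimum per-replicate methylation difference;
#' promoter gates r > 0.5, 4 hpf < 0.025, 36 hpf > 0.15, adult > 0.45,
#' adjusted p < 0.01; expression log2FC 1.5 at FDR 0.05 with 5 clusters;
#' splicing dPSI 15 (mean) / 5 (per pair) / 10 (per stage, markers).
#'
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory.
#' @param simulate A [sim_config()]; set `input_dir` instead to analyse an
#'   existing fixture bundle.
#' @param input_dir Optional path to a bundle written by
#'   [write_fixture_bundle()].
#' @param dmr,promoter,expression,splicing,summary Per-module parameter
#'   lists; unspecified entries keep the defaults above.
#' @return Nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = "pgc_run",
                            simulate = NULL, input_dir = NULL,
                            dmr = list(), promoter = list(),
                            expression = list(), splicing = list(),
                            summary = list()) {
  merge_defaults <- function(defaults, user) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir, input_dir = input_dir,
    simulate = if (is.null(simulate) && is.null(input_dir))
      sim_config(seed = seed) else simulate,
    dmr = merge_defaults(list(alpha_dmc = 1e-3, max_gap = 50, min_dmc = 5,
                              min_span = 50, low_cov_thresh = 5,
                              max_lowcov_frac = 0.25, min_delta = 0.1,
                              fdr_gate = FALSE), dmr),
    promoter = merge_defaults(list(r_min = 0.5, gate_4hpf = 0.025,
                                   gate_36hpf = 0.15, gate_adult = 0.45,
                                   padj_max = 0.01, stage_axis = "rank"),
                              promoter),
    expression = merge_defaults(list(lfc_min = 1.5, fdr_max = 0.05,
                                     pseudo_cpm = 0.5, k = 5,
                                     prior_df = 20), expression),
    splicing = merge_defaults(list(min_avg_dpsi = 15, min_pair_dpsi = 5,
                                   min_stage_dpsi = 10, marker_avg_dpsi = 15,
                                   marker_alpha = 0.05), splicing),
    summary = merge_defaults(list(bin_bp = 10000, hist_bins = 20,
                                  corr_bin_bp = 1000), summary))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$out_dir <- NULL    # where a run lands does not change what it computes
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                              digits = NA, null = "null", force = TRUE),
             tmp)
  unname(tools::md5sum(tmp))
}

wtsv <- function(x, path, rownames = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = rownames,
                     col.names = if (rownames) NA else TRUE)
  invisible(path)
}

#' Run the full PGC methylome/transcriptome pipeline
#'
#' Simulates (or loads) the input bundle, then runs methylome summaries,
#' stage-wise DMR calling (technical-replicate mode at 4 hpf), the
#' promoter 5mC-target screen, differential expression with marker calling,
#' clustering and conservation, and the differential exon rules. Each
#' stage writes TSVs under `out_dir`; a run manifest records the config
#' hash, seed and per-stage row counts. Reruns with the same config are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("need a pipeline_config")
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    stop("pre-flight validation: input_dir does not exist: ",
         config$input_dir)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  counts_of <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), file.path(out, paste0("failed/",
                                                            name)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(file.path(out, "failed"), showWarnings = FALSE)

  ## ---- inputs
  inputs <- stage("inputs", {
    if (is.null(config$input_dir)) {
      model <- build_genome_model(config$simulate)
      meth <- simulate_methylomes(model)
      tracks <- simulate_signal_tracks(model)
      expr <- simulate_expression(model)
      psi <- simulate_psi(model)
      write_fixture_bundle(model, meth, tracks, expr, psi,
                           file.path(out, "bundle"))
      list(model = model, meth = meth, tracks = tracks, expr = expr,
           psi = psi, repeats = model$regions$repeats,
           nmis = model$regions$nmis, tss = model$regions$tss,
           chrom_sizes = model$chrom_sizes)
    } else {
      dirp <- config$input_dir
      sheet <- utils::read.table(file.path(dirp, "samples.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
      sheet$stage <- as.character(sheet$stage)
      tabs <- lapply(sheet$sample_id, function(s)
        read_cpg_calls(file.path(dirp, "coverage", paste0(s, ".cov"))))
      names(tabs) <- sheet$sample_id
      cs <- utils::read.table(file.path(dirp, "chrom.sizes"), sep = "\t",
                              stringsAsFactors = FALSE)
      track_files <- list.files(file.path(dirp, "tracks"),
                                full.names = TRUE)
      tracks <- lapply(track_files, read_bedgraph)
      names(tracks) <- sub("\\.bedGraph$", "", basename(track_files))
      fp <- function(n) file.path(dirp, "expression", n)
      list(model = NULL, meth = list(samples = sheet, tables = tabs),
           tracks = tracks,
           expr = list(counts = read_counts_tsv(fp("counts.tsv")),
                       orthology = utils::read.table(fp("orthology.tsv"),
                                                     header = TRUE,
                                                     sep = "\t",
                                                     stringsAsFactors = FALSE),
                       fpkm_panels = list(
                         mouse = utils::read.table(fp("fpkm_mouse.tsv"),
                                                   header = TRUE, sep = "\t",
                                                   stringsAsFactors = FALSE),
                         human = utils::read.table(fp("fpkm_human.tsv"),
                                                   header = TRUE, sep = "\t",
                                                   stringsAsFactors = FALSE))),
           psi = read_psi_tsv(file.path(dirp, "splicing", "psi.tsv")),
           repeats = read_bed(file.path(dirp, "regions", "repeats.bed")),
           nmis = read_bed(file.path(dirp, "regions", "nmis.bed")),
           tss = read_bed(file.path(dirp, "regions", "tss.bed")),
           chrom_sizes = stats::setNames(as.integer(cs[[2]]),
                                         as.character(cs[[1]])))
    }
  })

  ## ---- methylome summaries
  stage("summaries", {
    sd_ <- file.path(out, "summaries")
    dir.create(sd_, showWarnings = FALSE)
    bm <- bin_methylomes(inputs$meth$tables, config$summary$bin_bp,
                         inputs$chrom_sizes)
    wtsv(cbind(bm$bins, round(bm$meth, 5)), file.path(sd_, "bins.tsv"))
    hists <- lapply(inputs$meth$tables, methylation_histogram,
                    n_bins = config$summary$hist_bins)
    hist_df <- cbind(hists[[1]][, c("lower", "upper")],
                     sapply(hists, `[[`, "count"))
    wtsv(hist_df, file.path(sd_, "histograms.tsv"))
    pca <- pca_samples(bm$meth, bm$valid)
    wtsv(data.frame(sample = rownames(pca$scores),
                    round(pca$scores[, 1:min(4, ncol(pca$scores)),
                                     drop = FALSE], 6)),
         file.path(sd_, "pca_scores.tsv"))
    wtsv(data.frame(component = seq_along(pca$var_explained),
                    var_explained = round(pca$var_explained, 6)),
         file.path(sd_, "pca_variance.tsv"))
    counts_of$summary_bins <- nrow(bm$bins)
  })

  ## ---- DMRs per stage
  dmr_all <- stage("dmr", {
    sheet <- inputs$meth$samples
    per_stage <- lapply(c("4", "7", "24", "36"), function(s) {
      pick <- function(tissue) {
        ids <- sheet$sample_id[sheet$tissue == tissue & sheet$stage == s]
        inputs$meth$tables[ids[order(ids)]]
      }
      mode <- if (any(sheet$replicate_type[sheet$stage == s] ==
                      "technical")) "technical" else "biological"
      res <- do.call(call_dmrs,
                     c(list(pgc = pick("PGC"), soma = pick("soma"),
                            repeats = inputs$repeats, mode = mode),
                       config$dmr))
      if (nrow(res$dmrs)) res$dmrs$stage <- s
      res$dmrs
    })
    dmrs <- do.call(rbind, per_stage)
    dd <- file.path(out, "dmr")
    dir.create(dd, showWarnings = FALSE)
    wtsv(dmrs, file.path(dd, "dmrs.tsv"))
    if (nrow(dmrs))
      write_bed(region_set(dmrs$chrom, dmrs$start, dmrs$end,
                           name = paste0(dmrs$stage, "_", dmrs$class),
                           score = dmrs$n_dmc),
                file.path(dd, "dmrs.bed"))
    counts_of$dmrs <- nrow(dmrs)
    dmrs
  })

  ## ---- promoter screen
  stage("promoters", {
    cand <- link_nmis_to_tss(inputs$nmis, inputs$tss)
    nm <- nmi_methylation(cand, inputs$meth$tables)
    scr <- do.call(screen_candidates,
                   c(list(nm = nm),
                     config$promoter[c("r_min", "gate_4hpf", "gate_36hpf",
                                       "gate_adult", "stage_axis")]))
    targets <- finalize_targets(scr, nm,
                                padj_max = config$promoter$padj_max)
    pd <- file.path(out, "promoters")
    dir.create(pd, showWarnings = FALSE)
    num <- vapply(targets, is.numeric, logical(1))
    targets[num] <- lapply(targets[num], function(x) signif(x, 6))
    wtsv(targets, file.path(pd, "candidates.tsv"))
    tt <- targets[targets$is_target, , drop = FALSE]
    if (nrow(tt))
      write_bed(region_set(tt$chrom, tt$start, tt$end, name = tt$gene_ids),
                file.path(pd, "targets.bed"))
    counts_of$promoter_targets <- sum(targets$is_target)
    counts_of$promoter_gated <- sum(targets$gates_pass)
  })

  ## ---- expression
  stage("expression", {
    ex <- inputs$expr
    de <- de_all_stages(ex$counts, lfc_min = config$expression$lfc_min,
                        fdr_max = config$expression$fdr_max,
                        pseudo_cpm = config$expression$pseudo_cpm,
                        prior_df = config$expression$prior_df)
    ed <- file.path(out, "expression")
    dir.create(ed, showWarnings = FALSE)
    for (s in names(de)) {
      d <- de[[s]]
      num <- vapply(d, is.numeric, logical(1))
      d[num] <- lapply(d[num], function(x) signif(x, 6))
      wtsv(d, file.path(ed, paste0("de_stage", s, ".tsv")))
    }
    markers <- call_consistent_markers(de)
    regulators <- call_consecutive_regulators(de)
    clusters <- if (length(regulators))
      cluster_dynamics(regulators, de, k = config$expression$k,
                       seed = config$seed) else NULL
    cons <- if (length(regulators))
      conservation_test(regulators, ex$orthology, ex$fpkm_panels)
      else NULL
    marker_tab <- data.frame(gene = regulators, stringsAsFactors = FALSE)
    marker_tab$consistent <- marker_tab$gene %in% markers
    if (!is.null(clusters))
      marker_tab$cluster <- clusters$cluster[match(marker_tab$gene,
                                                   clusters$gene)]
    if (!is.null(cons)) {
      for (sp in colnames(cons$per_gene))
        marker_tab[[paste0("conserved_", sp)]] <-
          cons$per_gene[match(marker_tab$gene, rownames(cons$per_gene)), sp]
      marker_tab$high_confidence <- marker_tab$gene %in% cons$high_confidence
      wtsv(cons$species, file.path(ed, "conservation.tsv"))
    }
    wtsv(marker_tab, file.path(ed, "markers.tsv"))
    counts_of$consistent_markers <- length(markers)
    counts_of$consecutive_regulators <- length(regulators)
  })

  ## ---- splicing
  stage("splicing", {
    psi <- inputs$psi
    covered <- filter_psi_coverage(psi)
    comps <- c("tissue@7", "tissue@24", "dev@PGC", "dev@soma")
    res <- lapply(comps, function(cmp)
      differential_exons(psi, cmp, events = covered,
                         min_avg_dpsi = config$splicing$min_avg_dpsi,
                         min_pair_dpsi = config$splicing$min_pair_dpsi))
    names(res) <- comps
    sd_ <- file.path(out, "splicing")
    dir.create(sd_, showWarnings = FALSE)
    for (cmp in comps) {
      d <- res[[cmp]]
      num <- vapply(d, is.numeric, logical(1))
      d[num] <- lapply(d[num], function(x) signif(x, 6))
      wtsv(d, file.path(sd_, paste0("diff_", gsub("[@]", "_", cmp),
                                    ".tsv")))
    }
    ov <- developmental_overlap_test(
      res[["dev@PGC"]]$event_id[res[["dev@PGC"]]$differential],
      res[["dev@soma"]]$event_id[res[["dev@soma"]]$differential], covered)
    wtsv(data.frame(overlap = ov$overlap, p = signif(ov$p, 6)),
         file.path(sd_, "dev_overlap.tsv"))
    mk <- tissue_marker_exons(psi, events = covered,
                              min_stage_dpsi = config$splicing$min_stage_dpsi,
                              min_avg_dpsi = config$splicing$marker_avg_dpsi,
                              alpha = config$splicing$marker_alpha)
    num <- vapply(mk, is.numeric, logical(1))
    mk[num] <- lapply(mk[num], function(x) signif(x, 6))
    wtsv(mk, file.path(sd_, "markers.tsv"))
    diff_any <- unique(unlist(lapply(res, function(d)
      d$event_id[d$differential])))
    counts_of$covered_events <- length(covered)
    counts_of$differential_exons <- length(diff_any)
    counts_of$marker_exons <- sum(mk$marker)
  })

  unlink(file.path(out, "failed"), recursive = TRUE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("pgcmethylome")),
                   seed = config$seed, config_hash = config_hash(config),
                   stage_counts = counts_of)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarise a pipeline run into report tables
#'
#' Regenerates compact summary TSVs (DMR stage-by-class counts, promoter
#' tier counts, marker counts, differential-exon counts) from the stage
#' outputs without recomputation.
#'
#' @param result_dir Directory written by [run_pipeline()].
#' @return Invisibly, a list of the report data frames.
#' @export
make_report <- function(result_dir) {
  need <- function(p) {
    fp <- file.path(result_dir, p)
    if (!file.exists(fp)) stop("missing stage output: ", p)
    fp
  }
  rd <- file.path(result_dir, "report")
  dir.create(rd, showWarnings = FALSE, recursive = TRUE)
  dmrs <- utils::read.table(need("dmr/dmrs.tsv"), header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  dmr_tab <- as.data.frame(table(stage = dmrs$stage, class = dmrs$class),
                           stringsAsFactors = FALSE)
  names(dmr_tab)[3] <- "n"
  wtsv(dmr_tab, file.path(rd, "dmr_stage_class.tsv"))
  cand <- utils::read.table(need("promoters/candidates.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  prom_tab <- as.data.frame(table(tier = cand$tier), stringsAsFactors = FALSE)
  names(prom_tab)[2] <- "n"
  wtsv(prom_tab, file.path(rd, "promoter_tiers.tsv"))
  mk <- utils::read.table(need("expression/markers.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  expr_tab <- data.frame(
    consecutive_regulators = nrow(mk),
    consistent_markers = sum(mk$consistent),
    high_confidence = if ("high_confidence" %in% names(mk))
      sum(mk$high_confidence) else NA_integer_)
  wtsv(expr_tab, file.path(rd, "expression_markers.tsv"))
  spl <- utils::read.table(need("splicing/markers.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  spl_tab <- data.frame(covered_events = nrow(spl),
                        marker_exons = sum(spl$marker))
  wtsv(spl_tab, file.path(rd, "splicing_markers.tsv"))
  invisible(list(dmr = dmr_tab, promoters = prom_tab,
                 expression = expr_tab, splicing = spl_tab))
}
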