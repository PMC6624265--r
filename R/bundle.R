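#' Write a complete simulated fixture bundle to disk
#'
#' Serialises a simulation into standard formats: one coverage file per
#' sample, BED region files, bedGraph tracks, counts/FPKM/orthology/PSI
#' TSVs, a machine-readable `truth.json` ledger and a checksum manifest.
#'
#' @param model A [build_genome_model()] result.
#' @param methylomes,tracks,expression,psi Outputs of the matching
#'   `simulate_*` functions.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_fixture_bundle <- function(model, methylomes, tracks, expression, psi,
                                 out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write to output directory: ", out_dir)
  sub <- function(d) {
    p <- file.path(out_dir, d)
    dir.create(p, showWarnings = FALSE, recursive = TRUE)
    p
  }
  covd <- sub("coverage"); regd <- sub("regions"); trkd <- sub("tracks")
  exprd <- sub("expression"); spld <- sub("splicing")

  for (s in names(methylomes$tables))
    write_cpg_calls(methylomes$tables[[s]],
                    file.path(covd, paste0(s, ".cov")))
  utils::write.table(methylomes$samples, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  write_bed(model$regions$repeats, file.path(regd, "repeats.bed"))
  write_bed(model$regions$nmis, file.path(regd, "nmis.bed"))
  write_bed(model$regions$tss, file.path(regd, "tss.bed"))
  utils::write.table(data.frame(chrom = names(model$chrom_sizes),
                                size = unname(model$chrom_sizes)),
                     file.path(out_dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  for (tn in names(tracks))
    write_bedgraph(tracks[[tn]], file.path(trkd, paste0(tn, ".bedGraph")))

  wt <- function(x, path, rn = TRUE)
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = rn,
                       col.names = NA)
  wt(expression$counts, file.path(exprd, "counts.tsv"))
  utils::write.table(expression$orthology,
                     file.path(exprd, "orthology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (sp in names(expression$fpkm_panels))
    utils::write.table(expression$fpkm_panels[[sp]],
                       file.path(exprd, paste0("fpkm_", sp, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ## PSI with interleaved quality columns, vast-tools style
  psi_out <- data.frame(event_id = rownames(psi$psi),
                        stringsAsFactors = FALSE)
  for (s in colnames(psi$psi)) {
    psi_out[[s]] <- round(psi$psi[, s], 2)
    psi_out[[paste0(s, ".Q")]] <- psi$qual[, s]
  }
  utils::write.table(psi_out, file.path(spld, "psi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth <- model$truth
  jsonlite::write_json(
    list(seed = truth$seed,
         n_planted = model$config$n_planted,
         regions = truth$regions, genes = truth$genes, exons = truth$exons),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a counts TSV (genes x samples) back into a matrix
#' @param path TSV written by [write_fixture_bundle()].
#' @return Integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' Read a PSI TSV with interleaved quality columns
#' @param path TSV written by [write_fixture_bundle()].
#' @return List with `psi`, `qual` matrices and `samples` data frame.
#' @export
read_psi_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  qcols <- grep("\\.Q$", names(df), value = TRUE)
  scols <- setdiff(names(df), c("event_id", qcols))
  psi <- as.matrix(df[, scols])
  qual <- as.matrix(df[, paste0(scols, ".Q")])
  rownames(psi) <- rownames(qual) <- df$event_id
  colnames(qual) <- scols
  parts <- strsplit(scols, "_")
  samples <- data.frame(tissue = vapply(parts, `[`, "", 1),
                        stage = as.numeric(vapply(parts, `[`, "", 2)),
                        replicate = as.integer(sub("^r", "",
                                                   vapply(parts, `[`, "", 3))),
                        sample_id = scols, stringsAsFactors = FALSE)
  list(psi = psi, qual = qual, samples = samples)
}
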