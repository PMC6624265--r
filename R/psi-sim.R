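#' Simulate percent-spliced-in (PSI) tables
#'
#' Eight samples (PGC and soma at 7 and 24 hpf, two replicates each).
#' Background events share a common PSI plus replicate noise; planted
#' differential events carry a tissue offset (PGC vs soma at both stages)
#' or a stage offset (24 vs 7 hpf in both tissues) of 20-40 PSI units.
#' Each cell gets a read-coverage quality code on the ordered scale
#' N < VLOW < LOW < OK < SOUND; a configurable fraction of background cells
#' falls below VLOW, while planted events are always adequately covered so
#' that truth is recoverable by construction.
#'
#' @param model A [build_genome_model()] result.
#' @return List with `psi` (event x sample matrix, \[0, 100\]), `qual`
#'   (matching character matrix of quality codes) and `samples`.
#' @export
simulate_psi <- function(model) {
  cfg <- model$config
  set.seed(cfg$seed + 4L)
  samples <- expand.grid(replicate = 1:2, stage = c(7, 24),
                         tissue = c("PGC", "soma"), stringsAsFactors = FALSE)
  samples <- samples[, c("tissue", "stage", "replicate")]
  samples$sample_id <- paste0(samples$tissue, "_", samples$stage, "_r",
                              samples$replicate)

  ex <- model$truth$exons
  n_bg <- cfg$n_psi_background
  ids <- c(ex$event_id, sprintf("bg%04d", seq_len(n_bg)))
  n <- length(ids)
  # planted bases sit mid-scale so a +/-40 offset cannot clip at 0 or 100
  base <- c(stats::runif(nrow(ex), 45, 55), stats::runif(n_bg, 5, 95))

  psi <- matrix(rep(base, 8), n, 8, dimnames = list(ids, samples$sample_id))
  for (i in seq_len(nrow(ex))) {
    if (ex$type[i] == "tissue") {
      psi[i, samples$tissue == "PGC"] <- psi[i, samples$tissue == "PGC"] +
        ex$offset[i]
    } else {
      psi[i, samples$stage == 24] <- psi[i, samples$stage == 24] +
        ex$offset[i]
    }
  }
  psi <- psi + stats::rnorm(length(psi), 0, cfg$psi_noise_sd)
  psi <- pmin(pmax(psi, 0), 100)

  codes <- c("N", "VLOW", "LOW", "OK", "SOUND")
  qual <- matrix(sample(codes[-1], n * 8, replace = TRUE), n, 8,
                 dimnames = dimnames(psi))
  bg_cells <- which(matrix(rep(!ids %in% ex$event_id, 8), n, 8) &
                    matrix(stats::runif(n * 8) < cfg$psi_lowqual_frac, n, 8))
  qual[bg_cells] <- "N"
  psi[qual == "N"] <- NA_real_

  list(psi = psi, qual = qual, samples = samples)
}
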