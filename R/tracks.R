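#' Simulate chromatin and hydroxymethylation signal tracks
#'
#' Produces bedGraph-style tracks (100 bp bins tiling each chromosome, last
#' bin truncated) for H3K4me1, H3K27ac, BioCAP and 5hmC. Background signal
#' is log-normal; bins overlapping planted DMRs get a per-region 3-10 fold
#' enrichment for the histone/BioCAP tracks, and 5hmC is enriched over the
#' late-hypermethylating (hyper24) regions only, so active-demethylation
#' profiles differ between the two DMR classes.
#'
#' @param model A [build_genome_model()] result.
#' @param bin_bp Track bin width in bp.
#' @return Named list of data frames (`chrom`, `start`, `end`, `value`),
#'   0-based half-open.
#' @export
simulate_signal_tracks <- function(model, bin_bp = 100) {
  cfg <- model$config
  set.seed(cfg$seed + 2L)
  bins <- do.call(rbind, lapply(names(model$chrom_sizes), function(ch) {
    sz <- model$chrom_sizes[[ch]]
    st <- seq(0L, sz - 1L, by = bin_bp)
    data.frame(chrom = ch, start = st, end = pmin(st + bin_bp, sz),
               stringsAsFactors = FALSE)
  }))
  gr_bins <- regions_to_granges(bins)

  tr <- model$truth$regions
  dmrs <- tr[tr$class %in% c("hypo4_dmr", "hyper24_dmr"), , drop = FALSE]
  hyper <- tr[tr$class == "hyper24_dmr", , drop = FALSE]

  enrich <- function(values, regions) {
    if (!nrow(regions)) return(values)
    fold <- stats::runif(nrow(regions), 3, 10)
    hits <- GenomicRanges::findOverlaps(gr_bins, regions_to_granges(regions))
    q <- S4Vectors::queryHits(hits)
    values[q] <- values[q] * fold[S4Vectors::subjectHits(hits)]
    values
  }
  make <- function(regions) {
    v <- stats::rlnorm(nrow(bins), meanlog = 0, sdlog = 0.5)
    cbind(bins, value = enrich(v, regions))
  }
  list(H3K4me1 = make(dmrs), H3K27ac = make(dmrs), BioCAP = make(dmrs),
       hmC5 = make(hyper))
}
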