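# Small, fast simulation shared across test files (built lazily, once).
tiny_cfg <- function(seed = 301, ...) {
  sim_config(genome_length = 1e6, n_genes = 120, n_nmi_promoters = 80,
             n_planted = list(hypo4_dmr = 6, hyper24_dmr = 6,
                              phylo_region = 6, promoter_target = 12,
                              consistent_marker = 8,
                              consecutive_regulator = 15, diff_exon = 12),
             n_conserved = 6, n_psi_background = 100, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fixture_env)) {
    if (!exists("model", envir = .fixture_env))
      assign("model", build_genome_model(tiny_cfg()), envir = .fixture_env)
    model <- get("model", envir = .fixture_env)
    val <- switch(name,
      model = model,
      meth = simulate_methylomes(model),
      tracks = simulate_signal_tracks(model),
      expr = simulate_expression(model),
      psi = simulate_psi(model))
    assign(name, val, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# group tables of one tissue/stage from a methylome fixture, replicate order
meth_group <- function(meth, tissue, stage) {
  sheet <- meth$samples
  ids <- sheet$sample_id[sheet$tissue == tissue & sheet$stage == stage]
  meth$tables[sort(ids)]
}

# fraction of regions in `truth` recovered by `called` at >= 50% reciprocal
# overlap
reciprocal_recovery <- function(truth, called, min_frac = 0.5) {
  if (!nrow(truth)) return(NA_real_)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    j <- which(called$chrom == truth$chrom[i] &
                 called$start < truth$end[i] & called$end > truth$start[i])
    any(vapply(j, function(k) {
      ov <- min(called$end[k], truth$end[i]) -
        max(called$start[k], truth$start[i])
      ov >= min_frac * (truth$end[i] - truth$start[i]) &&
        ov >= min_frac * (called$end[k] - called$start[k])
    }, logical(1)))
  }, logical(1))
  mean(hit)
}

# DMR bases falling outside any planted feature
false_dmr_bases <- function(called, truth_regions) {
  if (!nrow(called)) return(0)
  sum(vapply(seq_len(nrow(called)), function(k) {
    j <- which(truth_regions$chrom == called$chrom[k] &
                 truth_regions$start < called$end[k] &
                 truth_regions$end > called$start[k])
    ov <- if (length(j))
      sum(pmin(truth_regions$end[j], called$end[k]) -
            pmax(truth_regions$start[j], called$start[k])) else 0
    (called$end[k] - called$start[k]) - ov
  }, numeric(1)))
}
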