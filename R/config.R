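#' Simulation configuration
#'
#' Builds the configuration object consumed by [build_genome_model()] and the
#' `simulate_*` generators. Defaults describe a miniature two-chromosome
#' genome carrying the feature classes the analysis modules are designed to
#' detect: early-hypomethylated PGC regions, late-hypermethylated PGC regions,
#' developmentally demethylating ("phylotypic") regions, promoter
#' non-methylated islands (NMIs) that gain 5mC across development, stage-wise
#' PGC marker genes and differentially included exons.
#'
#' @param genome_length Total genome size in bp, split over `n_chrom`
#'   chromosomes.
#' @param n_chrom Number of chromosomes.
#' @param cpg_spacing_mean Mean spacing (bp) between background CpGs.
#' @param n_genes Number of genes (each contributes one TSS).
#' @param n_nmi_promoters Number of genes whose promoter carries an NMI.
#' @param repeat_fraction Fraction of the genome covered by repeat intervals.
#' @param coverage_mean Mean per-CpG read depth (negative binomial).
#' @param coverage_size Negative-binomial size (inverse dispersion) of depth.
#' @param bb_rho Beta-binomial intra-CpG overdispersion of methylation counts.
#' @param baseline_meth Genome-wide background methylated fraction.
#' @param n_planted Named list of planted feature counts; see Details.
#' @param island_spacing CpG spacing (bp) inside NMIs.
#' @param dmr_spacing CpG spacing (bp) inside planted DMR/phylo regions.
#' @param dmr_width_range Length range (bp) of planted DMR/phylo regions.
#' @param nmi_width_range Length range (bp) of NMIs.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of baseline gene means.
#' @param planted_meanlog,planted_sdlog Log-normal parameters of the baseline
#'   means of planted marker/regulator genes (kept moderate so a few dozen
#'   strongly PGC-elevated genes do not distort library composition).
#' @param expr_dispersion Negative-binomial dispersion of RNA counts.
#' @param marker_fc Fold change of consistent PGC markers (PGC over soma).
#' @param regulator_fc_range Fold-change range of consecutive-stage regulators.
#' @param n_conserved Number of regulators planted as conserved in both
#'   foreign species panels.
#' @param n_psi_background Number of background (non-differential) PSI events.
#' @param psi_noise_sd Replicate noise (PSI units) of PSI values.
#' @param psi_offset_range Planted PSI offset range (PSI units).
#' @param psi_lowqual_frac Fraction of background PSI cells with quality below
#'   `VLOW`.
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @details `n_planted` accepts the classes `hypo4_dmr` (hypomethylated in
#'   4 hpf PGCs), `hyper24_dmr` (hypermethylated in 24 hpf PGCs),
#'   `phylo_region` (demethylating in both tissues), `promoter_target` (NMI
#'   promoters gaining 5mC), `consistent_marker` (PGC-enriched at all four
#'   stages), `consecutive_regulator` (PGC-enriched in >= 2 consecutive
#'   stages) and `diff_exon` (differential exon inclusion).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5e6,
                       n_chrom = 2,
                       cpg_spacing_mean = 100,
                       n_genes = 400,
                       n_nmi_promoters = 300,
                       repeat_fraction = 0.10,
                       coverage_mean = 30,
                       coverage_size = 5,
                       bb_rho = 0.02,
                       baseline_meth = 0.80,
                       n_planted = list(),
                       island_spacing = 10,
                       dmr_spacing = 5,
                       dmr_width_range = c(400, 800),
                       nmi_width_range = c(200, 1000),
                       expr_meanlog = log(100),
                       expr_sdlog = 1,
                       planted_meanlog = log(50),
                       planted_sdlog = 0.5,
                       expr_dispersion = 0.1,
                       marker_fc = 8,
                       regulator_fc_range = c(6, 10),
                       n_conserved = 17,
                       n_psi_background = 300,
                       psi_noise_sd = 3,
                       psi_offset_range = c(20, 40),
                       psi_lowqual_frac = 0.05,
                       seed = 1L) {
  planted_default <- list(hypo4_dmr = 20, hyper24_dmr = 25, phylo_region = 40,
                          promoter_target = 30, consistent_marker = 16,
                          consecutive_regulator = 47, diff_exon = 30)
  unknown <- setdiff(names(n_planted), names(planted_default))
  if (length(unknown))
    stop("unknown planted feature class(es): ", paste(unknown, collapse = ", "))
  planted_default[names(n_planted)] <- n_planted

  cfg <- list(genome_length = genome_length, n_chrom = n_chrom,
              cpg_spacing_mean = cpg_spacing_mean, n_genes = n_genes,
              n_nmi_promoters = n_nmi_promoters,
              repeat_fraction = repeat_fraction,
              coverage_mean = coverage_mean, coverage_size = coverage_size,
              bb_rho = bb_rho, baseline_meth = baseline_meth,
              n_planted = planted_default,
              island_spacing = island_spacing, dmr_spacing = dmr_spacing,
              dmr_width_range = dmr_width_range,
              nmi_width_range = nmi_width_range,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              planted_meanlog = planted_meanlog,
              planted_sdlog = planted_sdlog,
              expr_dispersion = expr_dispersion, marker_fc = marker_fc,
              regulator_fc_range = regulator_fc_range,
              n_conserved = n_conserved,
              n_psi_background = n_psi_background,
              psi_noise_sd = psi_noise_sd,
              psi_offset_range = psi_offset_range,
              psi_lowqual_frac = psi_lowqual_frac,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  pos <- c("genome_length", "n_chrom", "cpg_spacing_mean", "coverage_mean",
           "coverage_size", "island_spacing", "dmr_spacing")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a single positive number")
  for (f in c("n_genes", "n_nmi_promoters"))
    if (cfg[[f]] < 0) stop("config field '", f, "' must be nonnegative")
  for (f in c("repeat_fraction", "bb_rho", "baseline_meth"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("config field '", f, "' must lie in (0, 1)")
  if (cfg$n_nmi_promoters > cfg$n_genes)
    stop("n_nmi_promoters cannot exceed n_genes")
  if (any(unlist(cfg$n_planted) < 0)) stop("planted counts must be nonnegative")
  if (cfg$n_planted$promoter_target > cfg$n_nmi_promoters)
    stop("promoter_target count cannot exceed n_nmi_promoters")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chrom, "chromosomes,", x$genome_length, "bp,",
      "seed", x$seed, "\n")
  cat("  planted:", paste(names(x$n_planted), unlist(x$n_planted),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}
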