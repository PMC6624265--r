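#' Sample size-matched control regions
#'
#' For each input region, places one control interval of exactly the same
#' length uniformly at random on the genome, rejecting placements that
#' overlap the excluded set (typically repeats plus the regions themselves)
#' or a previously placed control.
#'
#' @param regions Region set to match.
#' @param chrom_sizes Named vector of chromosome sizes.
#' @param excluded Region set of forbidden intervals.
#' @param seed Integer seed.
#' @param max_tries Placement attempts per region before giving up.
#' @return Region set of controls (same length multiset as `regions`).
#' @export
sample_matched_controls <- function(regions, chrom_sizes, excluded,
                                    seed = 1L, max_tries = 1000) {
  set.seed(seed)
  placed <- region_set()
  forbidden <- excluded
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    w <- regions$end[i] - regions$start[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(names(chrom_sizes), 1, prob = chrom_sizes)
      if (chrom_sizes[[ch]] <= w) next
      st <- floor(stats::runif(1, 0, chrom_sizes[[ch]] - w))
      if (!overlaps_any(ch, st, st + w, forbidden) &&
          !overlaps_any(ch, st, st + w, placed)) {
        cand <- region_set(ch, st, st + w, name = paste0("ctrl_", i))
        out[[i]] <- cand
        placed <- rbind(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not place control ", i, " (length ", w, ") after ",
           max_tries, " tries: excluded regions leave too little space")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# length-weighted mean track signal per region; NA where no track coverage
region_track_means <- function(track, regions) {
  if (!nrow(regions)) return(numeric())
  gr_t <- regions_to_granges(track)
  gr_r <- regions_to_granges(regions)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_t)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_r)[q],
                                          IRanges::ranges(gr_t)[s]))
  num <- tapply(track$value[s] * w, factor(q, levels = seq_len(nrow(regions))),
                sum)
  den <- tapply(w, factor(q, levels = seq_len(nrow(regions))), sum)
  out <- as.numeric(num) / as.numeric(den)
  out
}

# Welch t-test tolerating constant inputs
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 observations per group")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx + vy == 0) {
    d <- mean(x) - mean(y)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0))
  }
  ht <- stats::t.test(x, y)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Signal enrichment of regions versus matched controls
#'
#' Per-region signal is the length-weighted mean of overlapping track bins;
#' regions without track coverage are excluded with a warning. Groups are
#' compared with a two-sided Welch t-test.
#'
#' @param track bedGraph data frame (`chrom`, `start`, `end`, `value`).
#' @param regions,controls Region sets.
#' @return List with `region_means`, `control_means`, `t`, `p`.
#' @export
region_signal_enrichment <- function(track, regions, controls) {
  rm_ <- region_track_means(track, regions)
  cm_ <- region_track_means(track, controls)
  if (anyNA(rm_) || anyNA(cm_)) {
    warning(sum(is.na(rm_)) + sum(is.na(cm_)),
            " region(s) without track coverage excluded")
    rm_ <- rm_[!is.na(rm_)]; cm_ <- cm_[!is.na(cm_)]
  }
  ht <- welch_t(rm_, cm_)
  list(region_means = rm_, control_means = cm_, t = ht$t, p = ht$p)
}

#' Signal profile around region centres
#'
#' Bins a fixed window (`centre - flank`, `centre + flank`) into
#' `2 * flank / bin` bins and reports the length-weighted mean track signal
#' per bin per region. Regions whose window extends beyond a chromosome end
#' are excluded with a warning.
#'
#' @param track bedGraph data frame.
#' @param regions Region set.
#' @param flank Half-window size in bp; must be divisible by `bin`.
#' @param bin Profile bin width in bp.
#' @param chrom_sizes Named chromosome sizes (defaults to the track extent).
#' @return List with `profile` (regions x bins matrix), `window_means` and
#'   `excluded` (row indices of dropped regions).
#' @export
profile_signal <- function(track, regions, flank = 3000, bin = 300,
                           chrom_sizes = NULL) {
  if (flank %% bin != 0) stop("flank must be divisible by bin")
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(track$end, track$chrom, max)
    chrom_sizes <- stats::setNames(as.integer(chrom_sizes),
                                   names(chrom_sizes))
  }
  centre <- (regions$start + regions$end) %/% 2L
  lim <- chrom_sizes[regions$chrom]
  ok <- centre - flank >= 0 & centre + flank <= lim &
    !is.na(lim)
  excluded <- unname(which(!ok))
  if (length(excluded))
    warning(length(excluded),
            " region(s) closer than flank to a chromosome edge excluded")
  regions <- regions[ok, , drop = FALSE]
  centre <- centre[ok]
  n_bins <- 2L * flank %/% bin
  if (!nrow(regions))
    return(list(profile = matrix(numeric(), 0, n_bins),
                window_means = numeric(), excluded = excluded))
  grid <- expand.grid(b = seq_len(n_bins) - 1L, r = seq_len(nrow(regions)))
  st <- centre[grid$r] - flank + grid$b * bin
  pb <- region_set(regions$chrom[grid$r], st, st + bin)
  vals <- region_track_means(track, pb)
  profile <- matrix(vals, nrow(regions), n_bins, byrow = TRUE)
  rownames(profile) <- regions$name
  list(profile = profile,
       window_means = rowMeans(profile, na.rm = TRUE),
       excluded = excluded)
}

#' Compare signal profiles of two region sets
#'
#' Two-sided unpaired Wilcoxon rank-sum test on the per-region window mean
#' signal of the two sets (the sets may differ in size, so no pairing is
#' defined).
#'
#' @inheritParams profile_signal
#' @param regions_a,regions_b Region sets to compare.
#' @return List with `profile_a`, `profile_b`, `w`, `p`.
#' @export
compare_profiles <- function(track, regions_a, regions_b, flank = 3000,
                             bin = 300, chrom_sizes = NULL) {
  pa <- profile_signal(track, regions_a, flank, bin, chrom_sizes)
  pb <- profile_signal(track, regions_b, flank, bin, chrom_sizes)
  ht <- stats::wilcox.test(pa$window_means, pb$window_means, exact = FALSE)
  list(profile_a = pa, profile_b = pb, w = unname(ht$statistic),
       p = ht$p.value)
}
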