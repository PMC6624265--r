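#' Build a repeat-inclusive in silico reference
#'
#' Hard-masks repeat intervals in the genome to `N` and appends each repeat
#' consensus sequence as its own record, so reads from repetitive elements
#' align to a single canonical copy instead of multi-mapping across the
#' genome.
#'
#' @param genome_fa Path to the genome FASTA.
#' @param repeats Region set of repeat intervals (0-based half-open;
#'   overlapping intervals are merged before masking).
#' @param consensus_fa Path to the FASTA of canonical repeat consensus
#'   sequences.
#' @param out_fa Output FASTA path.
#' @return Invisibly, `out_fa`. Record count equals genome records plus
#'   consensus records.
#' @export
build_repeat_inclusive_reference <- function(genome_fa, repeats,
                                             consensus_fa, out_fa) {
  genome <- Biostrings::readDNAStringSet(genome_fa)
  names(genome) <- sub("\\s.*$", "", names(genome))
  consensus <- Biostrings::readDNAStringSet(consensus_fa)
  names(consensus) <- sub("\\s.*$", "", names(consensus))
  clash <- intersect(names(genome), names(consensus))
  if (length(clash))
    stop("consensus id(s) collide with chromosome name(s): ",
         paste(clash, collapse = ", "))
  if (nrow(repeats)) {
    bad <- !repeats$chrom %in% names(genome)
    if (any(bad))
      stop("repeat interval(s) on unknown chromosome: ",
           paste(unique(repeats$chrom[bad]), collapse = ", "))
    merged <- merge_regions(repeats)
    for (ch in unique(merged$chrom)) {
      mi <- merged[merged$chrom == ch, , drop = FALSE]
      if (any(mi$end > Biostrings::width(genome[ch])))
        stop("repeat interval beyond chromosome end on ", ch)
      at <- IRanges::IRanges(start = mi$start + 1L, end = mi$end)
      genome[[ch]] <- Biostrings::replaceAt(
        genome[[ch]], at,
        Biostrings::DNAStringSet(strrep("N", IRanges::width(at))))
    }
  }
  Biostrings::writeXStringSet(c(genome, consensus), out_fa)
  invisible(out_fa)
}
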