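#' Read per-CpG methylation calls
#'
#' Parses the 6-column "coverage" dialect produced by common methylation
#' extractors (`chrom start end pct_meth count_M count_U`, with
#' `start == end` at the 1-based CpG position) or a 4-column methylation
#' bedGraph (`chrom start end fraction`, 0-based half-open, unit weight).
#'
#' @param path File path (plain or gzipped).
#' @param dialect `"coverage6"` or `"bedGraph-meth"`.
#' @param lenient If `TRUE`, malformed lines are skipped with a warning that
#'   reports their line numbers; otherwise any malformed or duplicated line
#'   is an error.
#' @return A CpG call table: data frame with `chrom`, `pos` (1-based),
#'   `count_M`, `count_U`, sorted and unique on (`chrom`, `pos`).
#' @export
read_cpg_calls <- function(path, dialect = c("coverage6", "bedGraph-meth"),
                           lenient = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  if (!length(lines) || all(!nzchar(lines)))
    return(data.frame(chrom = character(), pos = integer(),
                      count_M = integer(), count_U = integer(),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- if (dialect == "coverage6") 6L else 4L
  nf <- lengths(fields)
  bad <- which(nf != want & nzchar(lines))
  parse_num <- function(k) suppressWarnings(
    as.numeric(vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_,
                      "")))
  if (dialect == "coverage6") {
    tab <- data.frame(chrom = vapply(fields, `[`, "", 1),
                      pos = parse_num(2), end = parse_num(3),
                      pct = parse_num(4), count_M = parse_num(5),
                      count_U = parse_num(6), stringsAsFactors = FALSE)
    bad <- union(bad, which(is.na(tab$pos) | is.na(tab$count_M) |
                            is.na(tab$count_U) | tab$count_M < 0 |
                            tab$count_U < 0))
  } else {
    tab <- data.frame(chrom = vapply(fields, `[`, "", 1),
                      start = parse_num(2), end = parse_num(3),
                      frac = parse_num(4), stringsAsFactors = FALSE)
    bad <- union(bad, which(is.na(tab$start) | is.na(tab$frac) |
                            tab$frac < 0 | tab$frac > 1))
  }
  bad <- sort(bad)
  if (length(bad)) {
    if (!lenient)
      stop("malformed line(s) in ", path, " at line number(s): ",
           paste(utils::head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "")
    warning("skipped ", length(bad), " malformed line(s) in ", path,
            " (line numbers: ", paste(utils::head(bad, 10), collapse = ", "),
            ")")
    tab <- tab[-bad, , drop = FALSE]
  }
  out <- if (dialect == "coverage6") {
    data.frame(chrom = tab$chrom, pos = as.integer(tab$pos),
               count_M = as.integer(tab$count_M),
               count_U = as.integer(tab$count_U), stringsAsFactors = FALSE)
  } else {
    # fraction track: represented at unit weight for summary use
    data.frame(chrom = tab$chrom, pos = as.integer(tab$start + 1L),
               count_M = tab$frac, count_U = 1 - tab$frac,
               stringsAsFactors = FALSE)
  }
  dup <- duplicated(out[, c("chrom", "pos")])
  if (any(dup)) {
    if (!lenient)
      stop("duplicated CpG position(s) in ", path, ": e.g. ",
           out$chrom[dup][1], ":", out$pos[dup][1])
    out <- out[!dup, , drop = FALSE]
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write a CpG call table in the 6-column coverage dialect
#' @param tab CpG call table.
#' @param path Output path (".gz" suffix gzips).
#' @export
write_cpg_calls <- function(tab, path) {
  cov <- tab$count_M + tab$count_U
  pct <- ifelse(cov > 0, 100 * tab$count_M / cov, 0)
  out <- data.frame(tab$chrom, tab$pos, tab$pos, round(pct, 4),
                    tab$count_M, tab$count_U)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a region set
#' @param path BED3-BED6 file.
#' @return Region set data frame (0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(utils::read.table(path, sep = "\t", header = FALSE,
                                    stringsAsFactors = FALSE,
                                    colClasses = "character"),
                  error = function(e) NULL)
  if (is.null(raw)) {
    if (length(readLines(path)) == 0) return(region_set())
    stop("malformed BED file: ", path)
  }
  if (ncol(raw) < 3) stop("malformed BED file (needs >= 3 columns): ", path)
  st <- suppressWarnings(as.integer(raw[[2]]))
  en <- suppressWarnings(as.integer(raw[[3]]))
  if (any(is.na(st) | is.na(en)))
    stop("malformed BED file (non-numeric coordinates): ", path)
  region_set(raw[[1]], st, en,
             name = if (ncol(raw) >= 4) raw[[4]] else NULL,
             score = if (ncol(raw) >= 5) suppressWarnings(as.numeric(raw[[5]]))
                     else NULL,
             strand = if (ncol(raw) >= 6) raw[[6]] else NULL)
}

#' Write a region set as BED6
#' @param df Region set.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end", "name", "score",
                            "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write bedGraph tracks
#' @param path bedGraph file.
#' @return Data frame `chrom`, `start`, `end`, `value` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4) stop("malformed bedGraph: ", path)
  data.frame(chrom = as.character(raw[[1]]), start = as.integer(raw[[2]]),
             end = as.integer(raw[[3]]), value = as.numeric(raw[[4]]),
             stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param track Track data frame.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(data.frame(track$chrom, track$start, track$end,
                                signif(track$value, 7)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
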