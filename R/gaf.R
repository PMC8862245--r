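## GAF (graph alignment format) parsing.
##
## GAF is tab-separated with 12 mandatory columns; the path column is a
## concatenation of ">seg" / "<seg" steps (orientation then segment id).
## Only the minimal dialect is used: per-base CIGARs (cg:Z) are ignored and
## coverage is interval-based on the path, matching how the depths are
## defined downstream.

#' Parse a GAF alignment file
#'
#' @param path GAF file (tab-separated, 12+ columns).
#' @param min_mapq records with mapping quality below this are dropped and
#'   counted (default 0 keeps everything; minigraph's minimal dialect).
#' @return data.table with one row per kept record: `qname`, `qlen`,
#'   `qstart`, `qend`, `strand`, `path_ids` (list), `path_orients` (list),
#'   `plen`, `pstart`, `pend`, `matches`, `block_len`, `mapq`.  The number
#'   of mapq-dropped records is attached as attribute `n_dropped`.
#' @export
parse_gaf <- function(path, min_mapq = 0L) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.table(qname = character(), qlen = integer(),
                      qstart = integer(), qend = integer(),
                      strand = character(), path_ids = list(),
                      path_orients = list(), plen = integer(),
                      pstart = integer(), pend = integer(),
                      matches = integer(), block_len = integer(),
                      mapq = integer())
    setattr(out, "n_dropped", 0L)
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 12L))
    stop("malformed GAF record at line ", which(nf < 12L)[1L],
         ": fewer than 12 columns")

  col <- function(i) vapply(f, `[[`, character(1), i)
  paths <- col(6L)
  steps <- regmatches(paths, gregexpr("[><][^><]+", paths))
  bad <- !vapply(steps, length, integer(1)) |
    vapply(steps, function(s) paste(s, collapse = ""), character(1)) != paths
  if (any(bad))
    stop("malformed GAF path column at line ", which(bad)[1L], ": ",
         paths[which(bad)[1L]])

  out <- data.table(
    qname = col(1L), qlen = as.integer(col(2L)),
    qstart = as.integer(col(3L)), qend = as.integer(col(4L)),
    strand = col(5L),
    path_ids = lapply(steps, function(s) substring(s, 2L)),
    path_orients = lapply(steps, function(s)
      ifelse(substr(s, 1L, 1L) == ">", "+", "-")),
    plen = as.integer(col(7L)), pstart = as.integer(col(8L)),
    pend = as.integer(col(9L)), matches = as.integer(col(10L)),
    block_len = as.integer(col(11L)), mapq = as.integer(col(12L))
  )
  if (any(out$pstart < 0L | out$pstart >= out$pend | out$pend > out$plen))
    stop("invalid path interval (need 0 <= pstart < pend <= plen) at line ",
         which(out$pstart < 0L | out$pstart >= out$pend |
                 out$pend > out$plen)[1L])
  keep <- out$mapq >= min_mapq
  dropped <- sum(!keep)
  out <- out[keep]
  setattr(out, "n_dropped", dropped)
  out
}

#' Write GAF records to a file
#'
#' Inverse of [parse_gaf()] for the 12 mandatory columns.
#'
#' @param records data.table as returned by [parse_gaf()].
#' @param path output file.
#' @export
write_gaf <- function(records, path) {
  path_str <- mapply(function(ids, ors)
    paste0(ifelse(ors == "+", ">", "<"), ids, collapse = ""),
    records$path_ids, records$path_orients)
  if (nrow(records) == 0L) path_str <- character()
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   records$qname, records$qlen, records$qstart,
                   records$qend, records$strand, path_str, records$plen,
                   records$pstart, records$pend, records$matches,
                   records$block_len, records$mapq)
  writeLines(lines, path)
  invisible(path)
}
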