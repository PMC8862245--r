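## rGFA graph model: parsing, validation, summary statistics and BED export.
##
## An rGFA file is GFA1 whose S-lines carry SN (stable sequence name),
## SO (0-based stable offset) and SR (assembly rank, 0 = primary) tags, as
## written by iterative minigraph construction.  Every segment is assigned an
## origin class from the prefix of its stable name, so that graphs combining
## a primary reference, alternative references and panel assemblies can be
## stratified by provenance.

#' Default stable-name prefix to origin-class map
#'
#' Origin classes: `REF_PRIMARY` (the anchoring reference, rank 0),
#' `REF_ALT_1` / `REF_ALT_2` (further reference assemblies), `PANEL`
#' (panel-line draft assemblies).  The map is configuration, not hard-coded:
#' names are contig-name prefixes (the part before the first underscore).
#' Unmatched prefixes fall back to `default_class` in [parse_rgfa()].
#'
#' @return named character vector prefix -> class.
#' @export
default_prefix_map <- function() {
  c(HdrR = "REF_PRIMARY", HNI = "REF_ALT_1", HSOK = "REF_ALT_2")
}

ORIGIN_CLASSES <- c("REF_PRIMARY", "REF_ALT_1", "REF_ALT_2", "PANEL")

## Extract an rGFA tag value ("SN:Z:x" etc.) from a list of tag fields.
rgfa_tag <- function(tags, key) {
  hit <- tags[startsWith(tags, paste0(key, ":"))]
  if (length(hit) == 0L) return(NA_character_)
  sub("^[A-Za-z0-9]+:[A-Za-z]:", "", hit[1L])
}

#' Parse an rGFA pangenome graph
#'
#' Reads GFA1 with SN/SO/SR segment tags, assigns each segment an origin
#' class by matching the prefix of its stable name (the part before the
#' first `_`) against `prefix_map`, and builds link and per-class indexes.
#' Links are stored once under a canonical orientation: a traversal in either
#' direction counts toward the same junction.
#'
#' @param path rGFA file.
#' @param prefix_map named character vector, stable-name prefix -> origin
#'   class (see [default_prefix_map()]).
#' @param default_class class assigned when no prefix matches (default
#'   `"PANEL"`).
#' @return a `pan_graph`: list with `segments` (data.table: id, sequence,
#'   length_bp, stable_name, stable_offset, rank_sr, origin_class), `links`
#'   (canonicalised data.table), and a per-stable-name ordered index of
#'   REF_PRIMARY segments.
#' @export
parse_rgfa <- function(path, prefix_map = default_prefix_map(),
                       default_class = "PANEL") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  rec_type <- substr(lines, 1L, 1L)

  s_idx <- which(rec_type == "S")
  l_idx <- which(rec_type == "L")

  parse_s <- function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed S-line at line ", i, ": fewer than 3 fields")
    tags <- f[-(1:3)]
    sn <- rgfa_tag(tags, "SN")
    so <- rgfa_tag(tags, "SO")
    sr <- rgfa_tag(tags, "SR")
    if (is.na(sn) || is.na(so) || is.na(sr))
      stop("S-line at line ", i, " (segment ", f[2L],
           ") is missing a required SN/SO/SR tag")
    seq <- if (f[3L] == "*") NA_character_ else f[3L]
    len <- if (!is.na(seq)) {
      nchar(seq)
    } else {
      ln <- rgfa_tag(tags, "LN")
      if (is.na(ln))
        stop("S-line at line ", i, " stores no sequence and no LN tag")
      as.integer(ln)
    }
    list(id = f[2L], sequence = seq, length_bp = as.integer(len),
         stable_name = sn, stable_offset = as.integer(so),
         rank_sr = as.integer(sr))
  }

  segs <- rbindlist(lapply(s_idx, parse_s))
  if (nrow(segs) == 0L) stop("no S-lines found in ", path)
  if (anyDuplicated(segs$id))
    stop("duplicate segment ids: ",
         paste(unique(segs$id[duplicated(segs$id)]), collapse = ", "))
  if (any(segs$stable_offset < 0)) stop("negative SO offset")
  if (any(segs$length_bp < 1)) stop("segment of length < 1")

  prefix <- sub("_.*$", "", segs$stable_name)
  cls <- unname(prefix_map[prefix])
  cls[is.na(cls)] <- default_class
  segs[, origin_class := factor(cls, levels = ORIGIN_CLASSES)]

  bad <- segs[(origin_class == "REF_PRIMARY") != (rank_sr == 0L)]
  if (nrow(bad) > 0L)
    stop("origin_class/rank inconsistency (REF_PRIMARY iff SR=0) for: ",
         paste(head(bad$id, 5L), collapse = ", "))

  links <- if (length(l_idx) > 0L) {
    lf <- tstrsplit(lines[l_idx], "\t", fixed = TRUE)
    if (length(lf) < 5L) stop("malformed L-line (fewer than 5 fields)")
    lk <- data.table(from_id = lf[[2L]], from_orient = lf[[3L]],
                     to_id = lf[[4L]], to_orient = lf[[5L]])
    bad_o <- !lk$from_orient %in% c("+", "-") | !lk$to_orient %in% c("+", "-")
    if (any(bad_o))
      stop("malformed L-line orientation at line ", l_idx[which(bad_o)[1L]])
    unknown <- setdiff(c(lk$from_id, lk$to_id), segs$id)
    if (length(unknown) > 0L)
      stop("L-line references unknown segment(s): ",
           paste(head(unknown, 5L), collapse = ", "))
    unique(canonical_link(lk$from_id, lk$from_orient, lk$to_id, lk$to_orient))
  } else {
    data.table(from_id = character(), from_orient = character(),
               to_id = character(), to_orient = character())
  }
  setkey(segs, id)

  g <- structure(list(segments = segs, links = links), class = "pan_graph")
  validate_pan_graph(g)
  g
}

## REF_PRIMARY segments ordered by stable coordinates, checked non-overlapping.
ref_index <- function(g) {
  ref <- g$segments[origin_class == "REF_PRIMARY"]
  setorder(ref, stable_name, stable_offset)
  ref
}

validate_pan_graph <- function(g) {
  ref <- ref_index(g)
  if (nrow(ref) > 1L) {
    ov <- ref[, {
      s <- stable_offset; e <- stable_offset + length_bp
      if (.N > 1L && any(s[-1L] < e[-.N])) stable_name[1L] else NULL
    }, by = stable_name]$V1
    if (length(ov) > 0L)
      stop("overlapping REF_PRIMARY segments on stable sequence(s): ",
           paste(ov, collapse = ", "))
  }
  invisible(g)
}

#' @export
print.pan_graph <- function(x, ...) {
  cat("pan_graph:", nrow(x$segments), "segments,", nrow(x$links), "links\n")
  print(x$segments[, .(n = .N, total_bp = sum(length_bp)), by = origin_class])
  invisible(x)
}

#' Write a pan_graph back to rGFA
#'
#' @param g a `pan_graph`.
#' @param path output file.
#' @export
write_rgfa <- function(g, path) {
  segs <- g$segments
  s_lines <- sprintf("S\t%s\t%s\tLN:i:%d\tSN:Z:%s\tSO:i:%d\tSR:i:%d",
                     segs$id,
                     ifelse(is.na(segs$sequence), "*", segs$sequence),
                     segs$length_bp, segs$stable_name, segs$stable_offset,
                     segs$rank_sr)
  l_lines <- if (nrow(g$links) > 0L) {
    sprintf("L\t%s\t%s\t%s\t%s\t0M", g$links$from_id, g$links$from_orient,
            g$links$to_id, g$links$to_orient)
  } else character()
  writeLines(c(s_lines, l_lines), path)
  invisible(path)
}

#' Per-origin-class graph summary statistics
#'
#' Segment count, total length, median length, longest segment and N50 per
#' origin class, plus an `All` row whose totals are the across-class sums.
#'
#' @param g a `pan_graph`.
#' @return data.table with one row per origin class present plus `All`.
#' @export
graph_stats <- function(g) {
  stopifnot(nrow(g$segments) > 0L)
  per <- g$segments[, .(
    n_segments = .N,
    total_bp = sum(as.numeric(length_bp)),
    median_bp = as.numeric(median(length_bp)),
    longest_bp = max(as.numeric(length_bp)),
    n50_bp = n50(length_bp)
  ), by = origin_class]
  setorder(per, origin_class)
  all_row <- g$segments[, .(
    origin_class = factor("All", levels = c(ORIGIN_CLASSES, "All")),
    n_segments = .N,
    total_bp = sum(as.numeric(length_bp)),
    median_bp = as.numeric(median(length_bp)),
    longest_bp = max(as.numeric(length_bp)),
    n50_bp = n50(length_bp)
  )]
  rbindlist(list(per, all_row))
}

#' Export REF_PRIMARY segments as BED intervals on stable coordinates
#'
#' Intervals are 0-based half-open `[stable_offset, stable_offset + length)`.
#'
#' @param g a `pan_graph`.
#' @param path optional file; when given, BED6 is written there.
#' @return data.table with BED6 columns (invisibly when `path` is given).
#' @export
export_segments_bed <- function(g, path = NULL) {
  ref <- ref_index(g)
  bed <- ref[, .(chrom = stable_name, start = stable_offset,
                 end = stable_offset + length_bp, name = id,
                 score = 0L, strand = "+")]
  if (!is.null(path)) {
    fwrite(bed, path, sep = "\t", col.names = FALSE)
    return(invisible(bed))
  }
  bed
}

## Concatenated REF_PRIMARY sequence over a stable interval [start, end).
## Requires the interval to be fully covered by reference segments carrying
## sequence.
stable_sequence <- function(g, chrom, start, end) {
  stopifnot(end > start)
  ref <- ref_index(g)[stable_name == chrom]
  hit <- ref[stable_offset < end & stable_offset + length_bp > start]
  if (nrow(hit) == 0L ||
      min(hit$stable_offset) > start ||
      max(hit$stable_offset + hit$length_bp) < end)
    stop("stable interval ", chrom, ":", start, "-", end,
         " is not fully covered by REF_PRIMARY segments")
  if (anyNA(hit$sequence))
    stop("REF_PRIMARY segments over ", chrom, ":", start, "-", end,
         " carry no sequence")
  pieces <- hit[, substr(sequence,
                         pmax(start - stable_offset, 0L) + 1L,
                         pmin(end - stable_offset, length_bp))]
  paste(pieces, collapse = "")
}
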