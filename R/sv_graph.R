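## Graph-derived structural variation: divergent alternative paths through
## bubbles, and large-scale deletions from junctions joining distant
## reference segments.

#' Default thresholds for alternative-path calling
#'
#' Defaults follow the strict published criteria: cumulative length
#' > 10 kb, at least one member segment diverging by more than 50%, DNA
#' support in >= 2 samples at 50% of that sample's reference mean depth,
#' RNA support in >= 8 samples at 10% of the RNA reference mean, and an
#' annotated exon overlapping the reference span.
#'
#' @param min_len minimum cumulative member length (bp, strict >).
#' @param min_divergence member divergence threshold (strict >).
#' @param divergence_mode `"any"` (a path qualifies if any member exceeds
#'   the divergence threshold) or `"all"`.
#' @param n_dna,dna_frac DNA support: number of samples and depth fraction.
#' @param dna_mode `"all"` (a sample supports only if every member is above
#'   threshold) or `"any"`.
#' @param n_rna,rna_frac RNA support: number of samples and depth fraction.
#' @param rna_mode `"any"` (default) or `"all"`.
#' @param min_exons minimum annotated exons overlapping the reference span.
#' @return named list of parameters.
#' @export
alt_path_params <- function(min_len = 10000, min_divergence = 0.5,
                            divergence_mode = c("any", "all"),
                            n_dna = 2, dna_frac = 0.5,
                            dna_mode = c("all", "any"),
                            n_rna = 8, rna_frac = 0.1,
                            rna_mode = c("any", "all"),
                            min_exons = 1) {
  list(min_len = min_len, min_divergence = min_divergence,
       divergence_mode = match.arg(divergence_mode),
       n_dna = n_dna, dna_frac = dna_frac, dna_mode = match.arg(dna_mode),
       n_rna = n_rna, rna_frac = rna_frac, rna_mode = match.arg(rna_mode),
       min_exons = min_exons)
}

#' Default thresholds for deletion calling
#'
#' Defaults follow the strict published criteria: two reference segments on
#' one stable sequence more than 10 kb apart, junction traversal count of
#' at least 50% of the sample's reference mean depth in at least half of
#' the panel samples, and at least one annotated exon fully contained in
#' the deleted interval.
#'
#' @param min_gap minimum stable-coordinate gap (bp, strict >).
#' @param junction_frac junction-count threshold as a fraction of ref_mean.
#' @param q minimum supporting samples; `NULL` means `ceiling(n_samples/2)`.
#' @param min_exons minimum fully-skipped exons (0 disables the criterion).
#' @return named list of parameters.
#' @export
deletion_params <- function(min_gap = 10000, junction_frac = 0.5, q = NULL,
                            min_exons = 1) {
  list(min_gap = min_gap, junction_frac = junction_frac, q = q,
       min_exons = min_exons)
}

## Undirected adjacency (segment id -> sorted neighbour ids) from the
## canonical link set; traversal ignores orientation because junction usage
## does.
graph_adjacency <- function(g) {
  lk <- g$links
  if (nrow(lk) == 0L) return(list())
  ends <- data.table(a = c(lk$from_id, lk$to_id), b = c(lk$to_id, lk$from_id))
  ends <- unique(ends[a != b])
  setorder(ends, a, b)
  split(ends$b, ends$a)
}

#' Enumerate candidate alternative paths (bubbles)
#'
#' Finds simple paths that start and end on REF_PRIMARY segments and
#' traverse only non-REF_PRIMARY segments in between, by bounded
#' depth-first search in deterministic lexicographic order.  Paths whose
#' two anchors lie on different stable sequences have no reference span and
#' are dropped (counted in attribute `n_cross_contig`).  If a search bound
#' is hit, the result carries attribute `truncated = TRUE`.
#'
#' @param g a `pan_graph`.
#' @param max_depth maximum number of member segments per path.
#' @param max_paths maximum number of candidate paths collected.
#' @return data.table: `anchor_left`, `anchor_right` (ordered by stable
#'   coordinates), `members` (list of member ids in left-to-right order),
#'   `n_members`, `cum_length`, `stable_name`, `span_start`, `span_end`
#'   (reference span between the anchors, half-open).
#' @export
enumerate_alt_paths <- function(g, max_depth = 50L, max_paths = 10000L) {
  segs <- g$segments
  is_ref <- setNames(segs$origin_class == "REF_PRIMARY", segs$id)
  adj <- graph_adjacency(g)
  ref_ids <- sort(segs[origin_class == "REF_PRIMARY", id])

  found <- new.env(parent = emptyenv())
  found$keys <- character()
  found$paths <- list()
  found$truncated <- FALSE

  record <- function(r1, members, r2) {
    if (r1 == r2) return(invisible())  ## out-and-back loops are artifacts
    fwd <- c(r1, members, r2)
    rev_ <- c(r2, rev(members), r1)
    canon <- if (paste(fwd, collapse = "\r") <= paste(rev_, collapse = "\r"))
      fwd else rev_
    key <- paste(canon, collapse = "\r")
    if (key %in% found$keys) return(invisible())
    if (length(found$keys) >= max_paths) {
      found$truncated <- TRUE
      return(invisible())
    }
    found$keys <- c(found$keys, key)
    found$paths[[length(found$paths) + 1L]] <-
      list(a1 = canon[1L], members = canon[-c(1L, length(canon))],
           a2 = canon[length(canon)])
    invisible()
  }

  dfs <- function(r1, path) {
    tip <- path[length(path)]
    for (nb in adj[[tip]] %||% character()) {
      if (is_ref[[nb]]) {
        if (length(path) > 1L) record(r1, path[-1L], nb)
      } else if (!(nb %in% path) && length(path) - 1L < max_depth) {
        dfs(r1, c(path, nb))
      }
    }
  }

  for (r in ref_ids) dfs(r, r)

  if (length(found$paths) == 0L) {
    out <- data.table(anchor_left = character(), anchor_right = character(),
                      members = list(), n_members = integer(),
                      cum_length = numeric(), stable_name = character(),
                      span_start = integer(), span_end = integer())
    setattr(out, "truncated", found$truncated)
    setattr(out, "n_cross_contig", 0L)
    return(out)
  }

  dt <- rbindlist(lapply(found$paths, function(p) {
    s1 <- segs[.(p$a1)]; s2 <- segs[.(p$a2)]
    if (s1$stable_name != s2$stable_name)
      return(data.table(anchor_left = NA_character_))
    ## orient anchors along stable coordinates
    if (s1$stable_offset <= s2$stable_offset) {
      left <- s1; right <- s2; mem <- p$members
    } else {
      left <- s2; right <- s1; mem <- rev(p$members)
    }
    data.table(anchor_left = left$id, anchor_right = right$id,
               members = list(mem), n_members = length(mem),
               cum_length = sum(as.numeric(segs[.(mem), length_bp])),
               stable_name = left$stable_name,
               span_start = left$stable_offset + left$length_bp,
               span_end = right$stable_offset)
  }), fill = TRUE)
  n_cross <- sum(is.na(dt$anchor_left))
  dt <- dt[!is.na(anchor_left)]
  setorder(dt, stable_name, span_start, anchor_left, anchor_right)
  setattr(dt, "truncated", found$truncated)
  setattr(dt, "n_cross_contig", n_cross)
  dt[]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

## Overlap of exons with a half-open span; a zero-width span (pure
## insertion point) overlaps an exon that strictly contains the point.
count_exon_overlap <- function(exons, chrom, s, e) {
  ex <- exons[exons$chrom == chrom, ]
  if (nrow(ex) == 0L) return(0L)
  if (e > s) sum(ex$start < e & ex$end > s)
  else sum(ex$start < s & ex$end > s)
}

#' Compute member-segment divergences for candidate paths
#'
#' Aligns each member segment against the slice of the reference span
#' proportional to its position along the path, using
#' [alignment_identity()].  Requires segment sequences in the graph.
#'
#' Note the saturation of unit-cost identity: two unrelated DNA sequences
#' of comparable length align at ~0.54 identity, so divergence measured
#' this way cannot exceed ~0.46 and an alternative-path divergence
#' criterion above 0.5 is never met by this internal fallback.  Divergence
#' values for calling should come from an external aligner-style table
#' passed to [call_alt_paths()] (the simulator records one).
#'
#' @param g a `pan_graph` with sequences.
#' @param candidates output of [enumerate_alt_paths()].
#' @return data.table `id`, `divergence` (one row per distinct member).
#' @export
path_divergences <- function(g, candidates) {
  ids <- unique(unlist(candidates$members))
  if (length(ids) == 0L)
    return(data.table(id = character(), divergence = numeric()))
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i]
    mem <- cand$members[[1L]]
    lens <- as.numeric(g$segments[.(mem), length_bp])
    cum <- cumsum(lens); tot <- cum[length(cum)]
    if (cand$span_end <= cand$span_start) next
    ref_seq <- stable_sequence(g, cand$stable_name, cand$span_start,
                               cand$span_end)
    w <- nchar(ref_seq)
    starts <- floor((cum - lens) / tot * w) + 1L
    ends <- pmax(ceiling(cum / tot * w), starts)
    rows[[i]] <- data.table(
      id = mem,
      divergence = vapply(seq_along(mem), function(j) {
        seq_j <- g$segments[.(mem[j]), sequence]
        if (is.na(seq_j))
          stop("segment ", mem[j], " carries no sequence; supply a ",
               "precomputed divergence table")
        1 - alignment_identity(seq_j, substr(ref_seq, starts[j],
                                             ends[j]))$identity
      }, numeric(1)))
  }
  out <- rbindlist(rows)
  if (nrow(out) == 0L)
    return(data.table(id = ids, divergence = NA_real_))
  out <- out[, .(divergence = max(divergence)), by = id]
  missing <- setdiff(ids, out$id)
  if (length(missing) > 0L)
    out <- rbind(out, data.table(id = missing, divergence = NA_real_))
  out[]
}

#' Call divergent alternative paths
#'
#' Applies the five calling criteria (cumulative length, member divergence,
#' DNA support, RNA support, exon overlap) to candidate bubbles.  All
#' thresholds come from [alt_path_params()].
#'
#' @param candidates output of [enumerate_alt_paths()].
#' @param divergences data.table `id`, `divergence` covering every member
#'   segment (e.g. from [path_divergences()] or an external aligner).
#' @param dna_profiles,rna_profiles lists of `coverage_profile`s.
#' @param annotation a `gene_annotation` from [load_annotation()] (or any
#'   list with an `exons` data.table: gene_id, chrom, start, end).
#' @param params list from [alt_path_params()].
#' @return data.table of calls (passing candidates) with evidence columns
#'   `max_divergence`, `dna_support`, `rna_support`, `exon_overlap`.  The
#'   full evidence table for all candidates, with per-criterion logical
#'   columns, is attached as attribute `evidence`.
#' @export
call_alt_paths <- function(candidates, divergences, dna_profiles,
                           rna_profiles, annotation,
                           params = alt_path_params()) {
  if (nrow(candidates) == 0L) {
    out <- copy(candidates)
    setattr(out, "evidence", copy(candidates))
    return(out)
  }
  div <- setNames(divergences$divergence, divergences$id)
  missing <- setdiff(unique(unlist(candidates$members)), names(div))
  missing <- union(missing,
                   names(div)[is.na(div)][names(div)[is.na(div)] %in%
                                            unlist(candidates$members)])
  if (length(missing) > 0L)
    stop("no divergence available for member segment(s): ",
         paste(head(sort(missing), 10L), collapse = ", "))

  support_count <- function(profiles, frac, mode) {
    vapply(seq_len(nrow(candidates)), function(i) {
      mem <- candidates$members[[i]]
      sum(vapply(profiles, function(p) {
        thr <- frac * p$ref_mean
        d <- p$depth[mem]
        if (mode == "all") all(d >= thr) else any(d >= thr)
      }, logical(1)))
    }, numeric(1))
  }

  ev <- copy(candidates)
  ev[, max_divergence := vapply(members, function(m)
    max(div[m]), numeric(1))]
  if (params$divergence_mode == "all")
    ev[, min_divergence_obs := vapply(members, function(m)
      min(div[m]), numeric(1))]
  ev[, dna_support := support_count(dna_profiles, params$dna_frac,
                                    params$dna_mode)]
  ev[, rna_support := support_count(rna_profiles, params$rna_frac,
                                    params$rna_mode)]
  ev[, exon_overlap := vapply(seq_len(.N), function(i)
    count_exon_overlap(annotation$exons, stable_name[i], span_start[i],
                       span_end[i]), integer(1))]

  ev[, pass_length := cum_length > params$min_len]
  div_stat <- if (params$divergence_mode == "any") ev$max_divergence
              else ev$min_divergence_obs
  ev[, pass_divergence := div_stat > params$min_divergence]
  ev[, pass_dna := dna_support >= params$n_dna]
  ev[, pass_rna := rna_support >= params$n_rna]
  ev[, pass_exon := exon_overlap >= params$min_exons]
  ev[, called := pass_length & pass_divergence & pass_dna & pass_rna &
       pass_exon]

  calls <- ev[called == TRUE,
              .(anchor_left, anchor_right, members, n_members, cum_length,
                stable_name, span_start, span_end, max_divergence,
                dna_support, rna_support, exon_overlap)]
  setorder(calls, stable_name, span_start, anchor_left)
  setattr(calls, "evidence", ev)
  calls[]
}

#' Call large-scale deletions from junction usage
#'
#' Candidate junctions join two REF_PRIMARY segments on one stable sequence
#' with consistent orientation (both `+` or both `-`); inversion-like links
#' are excluded and counted in attribute `n_inconsistent_orientation`.  A
#' candidate is called when the stable-coordinate gap exceeds `min_gap`,
#' the junction traversal count reaches `junction_frac * ref_mean` in at
#' least `q` samples, and at least `min_exons` annotated exons are fully
#' contained in the deleted interval.
#'
#' @param g a `pan_graph`.
#' @param dna_profiles list of `coverage_profile`s.
#' @param annotation a `gene_annotation` (needed when `min_exons > 0`).
#' @param params list from [deletion_params()].
#' @return data.table of calls: `upstream_id`, `downstream_id`,
#'   `stable_name`, `del_start`, `del_end`, `span_bp`, `n_support`,
#'   `exons_skipped`.  Full candidate evidence attached as attribute
#'   `evidence`.
#' @export
call_deletions <- function(g, dna_profiles, annotation = NULL,
                           params = deletion_params()) {
  segs <- g$segments
  q <- params$q %||% ceiling(length(dna_profiles) / 2)

  lk <- copy(g$links)
  empty <- data.table(upstream_id = character(), downstream_id = character(),
                      stable_name = character(), del_start = integer(),
                      del_end = integer(), span_bp = numeric(),
                      n_support = integer(), exons_skipped = integer())
  if (nrow(lk) == 0L) {
    setattr(empty, "evidence", copy(empty))
    return(empty)
  }
  lk[, `:=`(from_ref = segs[.(from_id), origin_class] == "REF_PRIMARY",
            to_ref = segs[.(to_id), origin_class] == "REF_PRIMARY")]
  lk <- lk[from_ref & to_ref]
  n_inconsistent <- 0L
  if (nrow(lk) > 0L) {
    n_inconsistent <- lk[from_orient != to_orient, .N]
    lk <- lk[from_orient == to_orient]
  }
  if (nrow(lk) == 0L) {
    setattr(empty, "evidence", copy(empty))
    setattr(empty, "n_inconsistent_orientation", n_inconsistent)
    return(empty)
  }

  lk[, `:=`(from_sn = segs[.(from_id), stable_name],
            to_sn = segs[.(to_id), stable_name])]
  lk <- lk[from_sn == to_sn]
  if (nrow(lk) > 0L) {
    lk[, `:=`(from_so = segs[.(from_id), stable_offset],
              from_len = segs[.(from_id), length_bp],
              to_so = segs[.(to_id), stable_offset],
              to_len = segs[.(to_id), length_bp])]
    lk[, upstream_id := ifelse(from_so <= to_so, from_id, to_id)]
    lk[, downstream_id := ifelse(from_so <= to_so, to_id, from_id)]
    lk[, del_start := ifelse(from_so <= to_so, from_so + from_len,
                             to_so + to_len)]
    lk[, del_end := ifelse(from_so <= to_so, to_so, from_so)]
    lk[, span_bp := as.numeric(del_end - del_start)]
    lk <- lk[span_bp > params$min_gap]
  }
  if (nrow(lk) == 0L) {
    setattr(empty, "evidence", copy(empty))
    setattr(empty, "n_inconsistent_orientation", n_inconsistent)
    return(empty)
  }

  keys <- link_key(lk$from_id, lk$from_orient, lk$to_id, lk$to_orient)
  lk[, n_support := vapply(keys, function(k)
    sum(vapply(dna_profiles, function(p) {
      cnt <- if (k %in% names(p$junctions)) p$junctions[[k]] else 0
      cnt >= params$junction_frac * p$ref_mean
    }, logical(1))), numeric(1))]

  lk[, exons_skipped := if (params$min_exons > 0 || !is.null(annotation)) {
    if (is.null(annotation))
      stop("annotation required when min_exons > 0")
    vapply(seq_len(.N), function(i) {
      ex <- annotation$exons[annotation$exons$chrom == from_sn[i], ]
      sum(ex$start >= del_start[i] & ex$end <= del_end[i])
    }, integer(1))
  } else 0L]

  lk[, `:=`(pass_support = n_support >= q,
            pass_exons = exons_skipped >= params$min_exons)]
  lk[, called := pass_support & pass_exons]
  lk[, stable_name := from_sn]

  calls <- lk[called == TRUE,
              .(upstream_id, downstream_id, stable_name, del_start, del_end,
                span_bp, n_support, exons_skipped)]
  setorder(calls, stable_name, del_start, del_end)
  setattr(calls, "evidence", lk)
  setattr(calls, "n_inconsistent_orientation", n_inconsistent)
  calls[]
}

#' Relaxed deletion scan
#'
#' [call_deletions()] with the gap threshold lowered to 1 kb and the exon
#' criterion disabled; a superset of the strict calls restricted to
#' span > 10 kb with skipped exons.
#'
#' @inheritParams call_deletions
#' @param min_gap relaxed gap threshold (default 1000 bp).
#' @export
relaxed_deletion_scan <- function(g, dna_profiles, annotation = NULL,
                                  params = deletion_params(), min_gap = 1000) {
  params$min_gap <- min_gap
  params$min_exons <- 0
  call_deletions(g, dna_profiles, annotation, params)
}
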