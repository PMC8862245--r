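## Synthetic pangenome graph with planted events and recorded ground truth.
##
## The reference backbone is one stable contig split into segments at event
## boundaries.  Alternative-path events are bubbles: anchor - reference
## allele - anchor on the reference, with a branch of panel segments whose
## sequences are mutated copies of reference-allele slices at calibrated
## divergence.  Deletion events are extra links joining the two reference
## segments flanking a run of skipped segments.  Decoys violate exactly one
## calling criterion each; the violated criterion is recorded in the truth.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a sequence to a target alignment identity
#'
#' Applies a substitution+insertion operator (a mutated base becomes three
#' random bases) at an intensity calibrated by bisection against
#' [alignment_identity()], because pure substitution cannot push unit-cost
#' identity below the ~0.54 random-sequence floor.  The mutation set is
#' nested in the intensity (shared random draws), making the realized
#' identity monotone in the knob and the bisection stable.
#'
#' @param ref source nucleotide string.
#' @param target_identity desired identity in (0.3, 1].
#' @param iters bisection iterations (default 10).
#' @param against sequence the identity is measured against (default the
#'   source itself; pass the detector's reference window to realize the
#'   divergence the detector will measure).
#' @return mutated string with attribute `realized_identity`.
#' @export
mutate_to_identity <- function(ref, target_identity, iters = 10L,
                               against = ref) {
  w <- nchar(ref)
  bases <- strsplit(ref, "")[[1L]]
  u <- runif(w)
  repl <- replicate(w, paste(sample(c("A", "C", "G", "T"), 3L,
                                    replace = TRUE), collapse = ""))
  apply_k <- function(k) {
    out <- bases
    hit <- u < k
    out[hit] <- repl[hit]
    paste(out, collapse = "")
  }
  ## calibrate on a capped prefix window (same draws) to keep the
  ## quadratic alignment cost down, then verify on the full sequence and
  ## nudge the intensity if needed
  calib_cap <- 1500L
  use_prefix <- identical(against, ref) && w > calib_cap
  ref_c <- if (use_prefix) substr(ref, 1L, calib_cap) else against
  apply_k_prefix <- function(k) {
    wc <- if (use_prefix) calib_cap else w
    out <- bases[seq_len(wc)]
    hit <- u[seq_len(wc)] < k
    out[hit] <- repl[seq_len(wc)][hit]
    paste(out, collapse = "")
  }
  measure_c <- function(k) alignment_identity(apply_k_prefix(k),
                                              ref_c)$identity
  ## bracket the intensity near the edit-script solution so that low
  ## divergence never evaluates the (long, costly) high-k mutants
  lo <- 0
  hi <- min(1, 3 * (1 - target_identity) / (1 + 2 * target_identity) + 0.05)
  while (hi < 1 && measure_c(hi) > target_identity) hi <- min(1, 2 * hi)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (measure_c(mid) > target_identity) lo <- mid else hi <- mid
  }
  k <- (lo + hi) / 2
  out <- apply_k(k)
  realized <- alignment_identity(out, against)$identity
  tries <- 0L
  while (abs(realized - target_identity) > 0.012 && tries < 4L) {
    k <- min(max(k + (realized - target_identity) * 0.7, 0), 1)
    out <- apply_k(k)
    realized <- alignment_identity(out, against)$identity
    tries <- tries + 1L
  }
  structure(out, realized_identity = realized)
}

ALT_DECOY_KINDS <- c("length", "divergence", "dna_support", "rna_support",
                     "exon")
DEL_DECOY_KINDS <- c("span", "junction_support", "exon_skip")

#' Simulate a pangenome graph with planted events
#'
#' @param cfg a [sim_config()].
#' @return a `panel_sim`: list with `graph` (a `pan_graph` with sequences),
#'   `layout` (reference path, per-event member indices, gene intervals —
#'   everything the read simulator needs), and `truth` (data.tables
#'   `alt_paths` and `deletions` with carriers and qualifying flags).
#' @export
simulate_graph <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  stopifnot(all(cfg$alt_decoys %in% ALT_DECOY_KINDS),
            all(cfg$del_decoys %in% DEL_DECOY_KINDS))

  env <- new.env(parent = emptyenv())
  env$segs <- list()
  env$links <- list()
  env$ref_path <- character()
  env$cursor <- 0L
  env$n <- 0L
  env$genes <- list()
  env$gene_n <- 0L
  env$divs <- list()

  add_seg <- function(id, seq, sn, so, sr) {
    env$segs[[length(env$segs) + 1L]] <- data.table(
      id = id, sequence = seq, length_bp = nchar(seq), stable_name = sn,
      stable_offset = so, rank_sr = sr)
    id
  }
  add_link <- function(a, b) {
    env$links[[length(env$links) + 1L]] <-
      data.table(from_id = a, from_orient = "+", to_id = b, to_orient = "+")
  }
  new_ref_seg <- function(len) {
    env$n <- env$n + 1L
    id <- sprintf("s%05d", env$n)
    add_seg(id, random_dna(len), cfg$contig, env$cursor, 0L)
    if (length(env$ref_path) > 0L)
      add_link(env$ref_path[length(env$ref_path)], id)
    env$ref_path <- c(env$ref_path, id)
    env$cursor <- env$cursor + len
    id
  }
  add_gene <- function(start, exon_starts, exon_len, strand = "+") {
    env$gene_n <- env$gene_n + 1L
    gid <- sprintf("gene%04d", env$gene_n)
    ex <- data.table(gene_id = gid, chrom = cfg$contig,
                     start = as.integer(exon_starts),
                     end = as.integer(exon_starts + exon_len))
    env$genes[[length(env$genes) + 1L]] <-
      list(gene_id = gid, chrom = cfg$contig, strand = strand,
           start = as.integer(start), end = max(ex$end) + 200L, exons = ex)
    gid
  }
  bg_gene_block <- function() {
    seg <- new_ref_seg(3000L)
    so <- env$cursor - 3000L
    add_gene(so + 200L, c(so + 400L, so + 1600L), 400L)
    seg
  }

  alt_truth <- list()
  del_truth <- list()
  layout_events <- list()

  make_alt_event <- function(kind) {
    ev <- sprintf("alt%02d", length(alt_truth) + 1L)
    span <- if (kind == "length") cfg$alt_decoy_span else cfg$alt_ref_span
    n_dna <- switch(kind, dna_support = cfg$alt_decoy_dna,
                    cfg$alt_dna_carriers)
    n_rna <- switch(kind, rna_support = cfg$alt_decoy_rna,
                    cfg$alt_rna_carriers)
    with_exon <- kind != "exon"

    anchor_l <- new_ref_seg(cfg$anchor_len)
    allele_id <- new_ref_seg(span)
    allele_idx <- length(env$ref_path)
    span_start <- env$cursor - span
    span_end <- env$cursor
    anchor_r <- new_ref_seg(cfg$anchor_len)

    ## member source slices of the reference allele; the divergent member
    ## is the short middle slice
    m <- cfg$alt_members
    w_hi <- max(500L, round(0.08 * span))
    w_lo <- floor((span - w_hi) / (m - 1L))
    widths <- rep(w_lo, m)
    hi_pos <- 2L
    widths[hi_pos] <- w_hi
    widths[m] <- span - sum(widths[-m])
    divs <- rep(if (kind == "divergence") cfg$alt_decoy_div
                else cfg$alt_lo_div, m)
    if (kind != "divergence") divs[hi_pos] <- cfg$alt_hi_div

    allele_seq <- env$segs[[length(env$segs) - 1L]]$sequence
    offs <- cumsum(widths) - widths
    slices <- substring(allele_seq, offs + 1L, offs + widths)

    ## member divergence is realized against the member's own source slice
    ## (that is also the divergence recorded in the truth and emitted as
    ## the external divergence table; see the methods vignette on the
    ## unit-cost identity floor)
    muts <- lapply(seq_len(m), function(j)
      mutate_to_identity(slices[j], 1 - divs[j]))
    realized <- vapply(muts, function(x)
      1 - attr(x, "realized_identity"), numeric(1))
    members <- character(m)
    for (j in seq_len(m)) {
      mid <- sprintf("%s_m%d", ev, j)
      add_seg(mid, as.character(muts[[j]]), sprintf("MIKK_%s_%d", ev, j),
              0L, 3L)
      members[j] <- mid
      env$divs[[length(env$divs) + 1L]] <-
        data.table(id = mid, divergence = realized[j])
    }
    src_start <- span_start + offs
    src_end <- span_start + offs + widths
    add_link(anchor_l, members[1L])
    for (j in seq_len(m - 1L)) add_link(members[j], members[j + 1L])
    add_link(members[m], anchor_r)

    if (with_exon)
      add_gene(span_start + 100L, span_start + 200L, 500L)

    dna_carriers <- sort(sample(cfg$samples, n_dna))
    rna_carriers <- sort(sample(cfg$rna_samples, n_rna))
    alt_truth[[length(alt_truth) + 1L]] <<- data.table(
      event_id = ev, kind = kind, qualifies = kind == "qualifying",
      anchor_left = anchor_l, anchor_right = anchor_r,
      members = list(members), stable_name = cfg$contig,
      span_start = span_start, span_end = span_end,
      target_divergence = list(divs), realized_divergence = list(realized),
      source_start = list(src_start), source_end = list(src_end),
      dna_carriers = list(dna_carriers), rna_carriers = list(rna_carriers),
      has_exon = with_exon)
    layout_events[[length(layout_events) + 1L]] <<- list(
      type = "alt", event_id = ev, allele_idx = allele_idx,
      members = members, dna_carriers = dna_carriers,
      rna_carriers = rna_carriers)
    invisible(ev)
  }

  make_del_event <- function(kind) {
    ev <- sprintf("del%02d", length(del_truth) + 1L)
    gap <- if (kind == "span") cfg$del_decoy_gap else cfg$del_gap
    n_car <- if (kind == "junction_support") cfg$del_decoy_carriers
             else cfg$del_carriers
    with_exon <- kind != "exon_skip"

    up <- new_ref_seg(cfg$anchor_len)
    del_start <- env$cursor
    n_mid <- if (gap > 6000L) 2L else 1L
    mid_len <- rep(floor(gap / n_mid), n_mid)
    mid_len[n_mid] <- gap - sum(mid_len[-n_mid])
    mids <- vapply(mid_len, new_ref_seg, character(1))
    mid_idx <- seq(length(env$ref_path) - n_mid + 1L, length(env$ref_path))
    del_end <- env$cursor
    down <- new_ref_seg(cfg$anchor_len)
    add_link(up, down)

    if (with_exon)
      add_gene(del_start + 100L, del_start + 300L, 400L)

    carriers <- sort(sample(cfg$samples, n_car))
    del_truth[[length(del_truth) + 1L]] <<- data.table(
      event_id = ev, kind = kind, qualifies = kind == "qualifying",
      upstream_id = up, downstream_id = down, stable_name = cfg$contig,
      del_start = del_start, del_end = del_end, gap_bp = gap,
      carriers = list(carriers), has_exon = with_exon)
    layout_events[[length(layout_events) + 1L]] <<- list(
      type = "del", event_id = ev, mid_idx = mid_idx,
      carriers = carriers)
    invisible(ev)
  }

  make_refalt_bubble <- function(i) {
    prefix <- if (i %% 2L == 1L) "HNI" else "HSOK"
    rank <- if (prefix == "HNI") 1L else 2L
    anchor_l <- new_ref_seg(cfg$anchor_len)
    allele_seq_len <- 400L
    allele_id <- new_ref_seg(allele_seq_len)
    span_start <- env$cursor - allele_seq_len
    anchor_r <- new_ref_seg(cfg$anchor_len)
    allele_seq <- env$segs[[length(env$segs) - 1L]]$sequence
    mut <- mutate_to_identity(allele_seq, 0.75)
    mid <- sprintf("ra%02d_m1", i)
    add_seg(mid, as.character(mut), sprintf("%s_%d", prefix, i), 0L, rank)
    env$divs[[length(env$divs) + 1L]] <-
      data.table(id = mid, divergence = 1 - attr(mut, "realized_identity"))
    add_link(anchor_l, mid)
    add_link(mid, anchor_r)
    invisible(mid)
  }

  ## ---- lay the contig out ----
  new_ref_seg(cfg$bg_seg_len)
  bg_gene_block()

  alt_kinds <- c(rep("qualifying", cfg$alt_qualifying), cfg$alt_decoys)
  del_kinds <- c(rep("qualifying", cfg$del_qualifying), cfg$del_decoys)
  n_bg_left <- max(cfg$n_bg_genes - 1L, 0L)
  for (k in alt_kinds) {
    make_alt_event(k)
    if (n_bg_left > 0L) { bg_gene_block(); n_bg_left <- n_bg_left - 1L }
    else new_ref_seg(cfg$bg_seg_len)
  }
  for (k in del_kinds) {
    make_del_event(k)
    if (n_bg_left > 0L) { bg_gene_block(); n_bg_left <- n_bg_left - 1L }
    else new_ref_seg(cfg$bg_seg_len)
  }
  for (i in seq_len(cfg$n_ref_alt_bubbles)) {
    make_refalt_bubble(i)
    new_ref_seg(cfg$bg_seg_len)
  }
  while (n_bg_left > 0L) { bg_gene_block(); n_bg_left <- n_bg_left - 1L }

  segs <- rbindlist(env$segs)
  prefix <- sub("_.*$", "", segs$stable_name)
  cls <- unname(default_prefix_map()[prefix])
  cls[is.na(cls)] <- "PANEL"
  segs[, origin_class := factor(cls, levels = ORIGIN_CLASSES)]
  setkey(segs, id)
  links <- unique(canonical_link(
    rbindlist(env$links)$from_id, rbindlist(env$links)$from_orient,
    rbindlist(env$links)$to_id, rbindlist(env$links)$to_orient))
  g <- structure(list(segments = segs, links = links), class = "pan_graph")
  validate_pan_graph(g)

  genes <- rbindlist(lapply(env$genes, function(x)
    data.table(gene_id = x$gene_id, chrom = x$chrom, strand = x$strand,
               start = x$start, end = x$end)))
  exons <- rbindlist(lapply(env$genes, `[[`, "exons"))

  structure(list(
    graph = g,
    layout = list(ref_path = env$ref_path, events = layout_events,
                  contig = cfg$contig, contig_len = env$cursor,
                  genes = genes, exons = exons),
    truth = list(alt_paths = rbindlist(alt_truth),
                 deletions = rbindlist(del_truth)),
    divergences = rbindlist(env$divs)
  ), class = "panel_sim")
}

#' @export
print.panel_sim <- function(x, ...) {
  cat("panel_sim:", nrow(x$graph$segments), "segments;",
      nrow(x$truth$alt_paths), "alt-path events (",
      sum(x$truth$alt_paths$qualifies), "qualifying );",
      nrow(x$truth$deletions), "deletion events (",
      sum(x$truth$deletions$qualifies), "qualifying )\n")
  invisible(x)
}
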