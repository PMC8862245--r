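## Simulated GAF alignments: per-sample read path intervals drawn over the
## sample's true haplotype path at Poisson depth.  Carriers route through
## alternative branches / deletion links, non-carriers through the
## reference; RNA reads are restricted to exonic spans plus, for carriers,
## the alternative branches.

## Haplotype path of one DNA sample: the reference path with the reference
## allele replaced by alt members for alt carriers, and skipped segments
## removed for deletion carriers.
sample_haplotype <- function(sim, sample_id) {
  hap <- as.list(sim$layout$ref_path)
  drop <- integer()
  for (ev in sim$layout$events) {
    if (ev$type == "alt" && sample_id %in% ev$dna_carriers)
      hap[[ev$allele_idx]] <- ev$members
    if (ev$type == "del" && sample_id %in% ev$carriers)
      drop <- c(drop, ev$mid_idx)
  }
  if (length(drop) > 0L) hap[drop] <- NULL
  unlist(hap)
}

## Draw read path intervals over an ordered segment path.
path_reads <- function(path_ids, seg_len, n_reads, read_len, qprefix) {
  lens <- unname(seg_len[path_ids])
  cum <- cumsum(lens)
  cum_start <- cum - lens
  total <- cum[length(cum)]
  starts <- floor(runif(n_reads, 0, max(total - 2, 1)))
  ends <- pmin(starts + read_len, total)
  i1 <- findInterval(starts, cum_start)
  i2 <- findInterval(ends - 1L, cum_start)
  data.table(
    qname = sprintf("%s_%06d", qprefix, seq_len(n_reads)),
    qlen = as.integer(ends - starts), qstart = 0L,
    qend = as.integer(ends - starts), strand = "+",
    path_ids = lapply(seq_len(n_reads), function(k)
      path_ids[i1[k]:i2[k]]),
    path_orients = lapply(seq_len(n_reads), function(k)
      rep("+", i2[k] - i1[k] + 1L)),
    plen = as.integer(cum[i2] - cum_start[i1]),
    pstart = as.integer(starts - cum_start[i1]),
    pend = as.integer(ends - cum_start[i1]),
    matches = as.integer(ends - starts),
    block_len = as.integer(ends - starts),
    mapq = 60L
  )
}

#' Simulate DNA and RNA GAF alignments
#'
#' DNA: reads of `cfg$read_len` at Poisson(`cfg$depth`) coverage over each
#' sample's haplotype path.  RNA: reads over annotated exon spans on the
#' reference at `cfg$rna_exon_depth`, plus full-branch reads over
#' alternative members for RNA carriers; non-exonic segments get no RNA
#' coverage.
#'
#' @param cfg a [sim_config()].
#' @param sim a `panel_sim` from [simulate_graph()].
#' @return list with `dna` and `rna`: named lists (by sample) of GAF record
#'   data.tables in the layout of [parse_gaf()].
#' @export
simulate_gaf <- function(cfg, sim) {
  set.seed(derive_seed(cfg$seed, 2L))
  segs <- sim$graph$segments
  seg_len <- setNames(as.numeric(segs$length_bp), segs$id)

  dna <- setNames(vector("list", cfg$n_samples), cfg$samples)
  for (s in cfg$samples) {
    hap <- sample_haplotype(sim, s)
    total <- sum(seg_len[hap])
    n_reads <- rpois(1L, total * cfg$depth / cfg$read_len)
    dna[[s]] <- path_reads(hap, seg_len, n_reads, cfg$read_len,
                           paste0(s, "_dna"))
  }

  ## reference-coordinate lookup for exon reads: the reference path is
  ## contiguous so a segment's span on the path equals its stable interval
  ref_path <- sim$layout$ref_path
  exons <- sim$layout$exons
  rna <- setNames(vector("list", cfg$n_rna_samples), cfg$rna_samples)
  for (r in cfg$rna_samples) {
    recs <- list()
    for (e in seq_len(nrow(exons))) {
      ex_len <- exons$end[e] - exons$start[e]
      n <- rpois(1L, max(ex_len, cfg$rna_read_len) * cfg$rna_exon_depth /
                   cfg$rna_read_len)
      if (n == 0L) next
      st <- exons$start[e] + floor(runif(n, 0, ex_len))
      en <- pmin(st + cfg$rna_read_len, sim$layout$contig_len)
      sub <- path_reads_at(ref_path, seg_len, st, en,
                           sprintf("%s_ex%03d", r, e))
      recs[[length(recs) + 1L]] <- sub
    }
    for (ev in sim$layout$events) {
      if (ev$type == "alt" && r %in% ev$rna_carriers) {
        mlen <- sum(seg_len[ev$members])
        recs[[length(recs) + 1L]] <- data.table(
          qname = sprintf("%s_%s_branch%d", r, ev$event_id, 1:3),
          qlen = as.integer(mlen), qstart = 0L, qend = as.integer(mlen),
          strand = "+",
          path_ids = rep(list(ev$members), 3L),
          path_orients = rep(list(rep("+", length(ev$members))), 3L),
          plen = as.integer(mlen), pstart = 0L, pend = as.integer(mlen),
          matches = as.integer(mlen), block_len = as.integer(mlen),
          mapq = 60L)
      }
    }
    rna[[r]] <- rbindlist(recs)
  }
  list(dna = dna, rna = rna)
}

## Reads with explicit genomic start/end positions on a contiguous path.
path_reads_at <- function(path_ids, seg_len, starts, ends, qprefix) {
  lens <- unname(seg_len[path_ids])
  cum <- cumsum(lens)
  cum_start <- cum - lens
  n <- length(starts)
  i1 <- findInterval(starts, cum_start)
  i2 <- findInterval(ends - 1L, cum_start)
  data.table(
    qname = sprintf("%s_%04d", qprefix, seq_len(n)),
    qlen = as.integer(ends - starts), qstart = 0L,
    qend = as.integer(ends - starts), strand = "+",
    path_ids = lapply(seq_len(n), function(k) path_ids[i1[k]:i2[k]]),
    path_orients = lapply(seq_len(n), function(k)
      rep("+", i2[k] - i1[k] + 1L)),
    plen = as.integer(cum[i2] - cum_start[i1]),
    pstart = as.integer(starts - cum_start[i1]),
    pend = as.integer(ends - cum_start[i1]),
    matches = as.integer(ends - starts),
    block_len = as.integer(ends - starts),
    mapq = 60L
  )
}
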