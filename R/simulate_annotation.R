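## Simulated annotation artifacts: GFF3 genes, CpG-island and repeat BEDs,
## pLI table and per-sample SV call sets with recorded ground truth.

#' Simulate annotation inputs (GFF3, islands, repeats, pLI, SVs)
#'
#' Gene and exon intervals come from the graph layout (they are placed
#' relative to planted events).  Repeats tile the reference at the
#' configured base fraction.  SV call sets are drawn per type with a
#' carrier-frequency spectrum dominated by singletons and a per-type
#' designed repeat-overlap fraction, realized by placing overlapping SVs
#' inside repeat intervals and the rest inside repeat-free gaps.  CpG
#' islands are split between TSS-anchored (where DMRs are planted) and
#' TSS-distal ones.
#'
#' @param cfg a [sim_config()].
#' @param sim a `panel_sim` from [simulate_graph()].
#' @return list with `genes`, `exons`, `islands` (with truth column `dmr`),
#'   `repeats`, `pli`, `svs` (per-sample long table) and `truth` (distinct
#'   SVs with carriers and repeat-overlap flags; realized repeat fraction).
#' @export
simulate_annotation <- function(cfg, sim) {
  set.seed(derive_seed(cfg$seed, 3L))
  L <- sim$layout$contig_len
  contig <- sim$layout$contig
  genes <- copy(sim$layout$genes)
  genes[, tss := ifelse(strand == "-", end - 1L, start)]
  exons <- copy(sim$layout$exons)

  ## repeats: fixed-width tiles on a regular grid hit the target base
  ## fraction exactly up to rounding
  rpt_w <- 400L
  n_rpt <- round(cfg$repeat_fraction * L / rpt_w)
  sp <- floor(L / n_rpt)
  rpt_start <- (seq_len(n_rpt) - 1L) * sp
  repeats <- data.table(chrom = contig, start = rpt_start,
                        end = rpt_start + rpt_w)

  ## pLI: U-shaped mixture, with the boundary values 0 and 1 present
  pli <- data.table(gene_id = genes$gene_id,
                    pli = round(rbeta(nrow(genes), 0.2, 0.2), 6))
  if (nrow(pli) >= 2L) pli$pli[1:2] <- c(1, 0)

  ## SVs: distinct events with carrier sets; per-type repeat overlap by
  ## construction (overlapping SVs start inside a repeat tile, the rest sit
  ## centred in repeat-free gaps)
  sv_samples <- sprintf("SV%02d", seq_len(cfg$sv_samples))
  gap_w <- sp - rpt_w
  truth_sv <- list()
  svs <- list()
  sv_id <- 0L
  for (tp in names(cfg$sv_repeat_design)) {
    ## one repeat tile per SV keeps distinct events unmergeable, so the
    ## per-type count is bounded by the reference length
    n <- min(cfg$sv_n_per_type, n_rpt - 2L)
    n_ov <- round(cfg$sv_repeat_design[[tp]] * n)
    tiles <- sample(n_rpt - 2L, n) ## one tile per SV, no reuse
    for (i in seq_len(n)) {
      sv_id <- sv_id + 1L
      overlap <- i <= n_ov
      tile0 <- (tiles[i] - 1L) * sp
      if (overlap) {
        st <- tile0 + 100L
      } else {
        st <- tile0 + rpt_w + 200L
      }
      len <- if (tp == "INS") sample(100:1000, 1L)
             else sample(200:min(1000, gap_w - 400L), 1L)
      en <- if (tp == "INS") st + 1L else st + len
      n_car <- 1L + rbinom(1L, cfg$sv_samples - 1L, 0.15)
      carriers <- sort(sample(sv_samples, n_car))
      chrom2 <- pos2 <- NA
      if (tp == "TRA") {
        tile2 <- sample(n_rpt - 2L, 1L)
        chrom2 <- contig
        pos2 <- (tile2 - 1L) * sp + rpt_w + floor(gap_w / 2)
      }
      truth_sv[[sv_id]] <- data.table(
        sv_id = sprintf("sv%04d", sv_id), chrom = contig, start = st,
        end = en, type = tp, length_bp = len,
        carriers = list(carriers), n_carriers = n_car,
        repeat_overlap = overlap)
      jit <- function(k) as.integer(round(rnorm(k, 0, 4)))
      nc <- length(carriers)
      svs[[sv_id]] <- data.table(
        chrom = contig,
        start = pmax(st + (if (tp == "INS") 0L else jit(nc)), 0L),
        end = en + (if (tp == "INS") 0L else jit(nc)),
        type = tp, length_bp = len, sample_id = carriers,
        chrom2 = chrom2, pos2 = pos2)
    }
  }
  svs <- rbindlist(svs)
  svs[end <= start, end := start + 1L]
  truth_sv <- rbindlist(truth_sv)

  ## CpG islands: DMR islands anchored at gene TSSs, the rest on a distal
  ## grid beyond the genes
  n_dmr <- min(cfg$meth_n_dmr, nrow(genes))
  tss_pick <- sort(sample(nrow(genes), n_dmr))
  isl_dmr <- data.table(chrom = contig,
                        start = pmax(genes$tss[tss_pick] - 250L, 0L),
                        end = genes$tss[tss_pick] + 250L,
                        dmr = TRUE)
  n_far <- cfg$meth_n_islands - n_dmr
  far0 <- L + 10000L
  isl_far <- data.table(chrom = contig,
                        start = far0 + (seq_len(n_far) - 1L) * 1500L,
                        end = far0 + (seq_len(n_far) - 1L) * 1500L + 500L,
                        dmr = FALSE)
  islands <- rbind(isl_dmr, isl_far)
  setorder(islands, chrom, start)
  islands[, name := sprintf("cgi%05d", .I)]

  realized_rpt <- sum(repeats$end - repeats$start) / L
  list(genes = genes, exons = exons, islands = islands, repeats = repeats,
       pli = pli, svs = svs,
       truth = list(distinct_svs = truth_sv,
                    repeat_fraction = realized_rpt))
}

#' Write a gene annotation as GFF3
#'
#' Emits gene, mRNA (one per gene), exon and CDS features; coordinates are
#' converted from internal 0-based half-open to GFF3 1-based closed.
#'
#' @param genes data.table `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @param exons data.table `gene_id`, `chrom`, `start`, `end`.
#' @param path output file.
#' @export
write_gff3 <- function(genes, exons, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    tid <- paste0(gid, ".t1")
    ex <- exons[gene_id == gid]
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              genes$chrom[i], genes$start[i] + 1L, genes$end[i],
              genes$strand[i], gid),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              genes$chrom[i], genes$start[i] + 1L, genes$end[i],
              genes$strand[i], tid, gid),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              ex$chrom, ex$start + 1L, ex$end, genes$strand[i], tid),
      sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              ex$chrom, ex$start + 1L, ex$end, genes$strand[i], gid, tid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param dt data.table with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @param path output file.
#' @export
write_bed <- function(dt, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(dt))
  fwrite(dt[, ..cols], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write per-sample SV calls as a minimal VCF
#'
#' One file per sample with SVTYPE/SVLEN/END (and CHR2/POS2 for TRA) INFO
#' keys.
#'
#' @param svs long SV table (see [simulate_annotation()]).
#' @param dir output directory; files are `sv_<sample>.vcf`.
#' @export
write_sv_vcf <- function(svs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in sort(unique(svs$sample_id))) {
    sub <- svs[sample_id == s]
    hdr <- c("##fileformat=VCFv4.2",
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
      "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
      "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"TRA chrom 2\">",
      "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"TRA pos 2\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      sprintf("##contig=<ID=%s>", unique(sub$chrom)),
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", s))
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", sub$type, sub$length_bp,
                    sub$end)
    tra <- sub$type == "TRA" & !is.na(sub$chrom2)
    info[tra] <- paste0(info[tra], sprintf(";CHR2=%s;POS2=%d",
                                           sub$chrom2[tra], sub$pos2[tra]))
    body <- sprintf("%s\t%d\tsv%d\tN\t<%s>\t.\tPASS\t%s\tGT\t1/1",
                    sub$chrom, sub$start + 1L, seq_len(nrow(sub)),
                    sub$type, info)
    writeLines(c(hdr, body), file.path(dir, paste0("sv_", s, ".vcf")))
  }
  invisible(dir)
}
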