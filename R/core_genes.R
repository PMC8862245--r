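## Core-gene classification: a gene is "core" when over 95% of its
## coding-exon bases fall inside reference segments used by every panel
## sample, "absent" when none do, and "fragmented" otherwise.

#' Load a gene annotation from GFF3
#'
#' Reads gene/mRNA/CDS features, maps CDS to genes through their transcript
#' parents (or directly when CDS point at genes), merges intervals per gene
#' across transcripts, and converts GFF3 1-based closed coordinates to
#' internal 0-based half-open ones.  The TSS is the leftmost coordinate on
#' the `+` strand and the rightmost on `-`.
#'
#' @param path GFF3 file.
#' @param feature `"CDS"` (default; coding exons) or `"exon"`.
#' @return a `gene_annotation`: list with `genes` (data.table: gene_id,
#'   chrom, strand, tss, gene_start, gene_end, exon_bp) and `exons`
#'   (data.table: gene_id, chrom, start, end; merged, disjoint per gene).
#' @export
load_annotation <- function(path, feature = c("CDS", "exon")) {
  feature <- match.arg(feature)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)

  gi <- which(typ == "gene")
  if (length(gi) == 0L) stop("no gene features in ", path)
  genes <- data.table(
    gene_id = as.character(md$ID[gi]),
    chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
    strand = as.character(GenomicRanges::strand(gr)[gi]),
    gene_start = GenomicRanges::start(gr)[gi] - 1L,
    gene_end = GenomicRanges::end(gr)[gi]
  )
  genes[, tss := ifelse(strand == "-", gene_end - 1L, gene_start)]

  first_parent <- function(idx) {
    p <- md$Parent[idx]
    vapply(as.list(p), function(x)
      if (length(x) == 0L) NA_character_ else as.character(x[[1L]]),
      character(1))
  }
  ti <- which(typ %in% c("mRNA", "transcript"))
  tx2gene <- setNames(first_parent(ti), as.character(md$ID[ti]))

  ci <- which(typ == feature)
  if (length(ci) == 0L)
    stop("no ", feature, " features in ", path)
  parent <- first_parent(ci)
  gene_of <- ifelse(parent %in% names(tx2gene), tx2gene[parent],
                    ifelse(parent %in% genes$gene_id, parent, NA_character_))
  if (anyNA(gene_of)) {
    warning(sum(is.na(gene_of)), " ", feature,
            " feature(s) without a resolvable parent gene were skipped")
    ci <- ci[!is.na(gene_of)]
    gene_of <- gene_of[!is.na(gene_of)]
  }

  ex <- data.table(gene_id = unname(gene_of),
                   chrom = as.character(GenomicRanges::seqnames(gr)[ci]),
                   start = GenomicRanges::start(gr)[ci] - 1L,
                   end = GenomicRanges::end(gr)[ci])
  ## merge per gene across transcripts
  ex <- ex[, {
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
    .(chrom = chrom[1L], start = IRanges::start(ir) - 1L,
      end = IRanges::end(ir))
  }, by = gene_id]

  genes <- merge(genes,
                 ex[, .(exon_bp = sum(end - start)), by = gene_id],
                 by = "gene_id", all.x = TRUE)
  genes[is.na(exon_bp), exon_bp := 0L]
  setorder(genes, chrom, gene_start)
  setorder(ex, chrom, start)
  structure(list(genes = genes[], exons = ex[]), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,", nrow(x$exons),
      "merged exon intervals\n")
  invisible(x)
}

#' Core segments: used by every sample
#'
#' The set of segment ids used by all samples in a usage matrix.  With
#' `include_ref = TRUE` every REF_PRIMARY segment is added regardless of
#' read support ("present by definition of the reference"); this makes
#' every reference-anchored gene trivially fully covered, so the default
#' keeps the read-support requirement for reference segments too — that is
#' what renders the core/fragmented/absent classification informative.
#'
#' @param usage logical matrix from [usage_matrix()].
#' @param g the `pan_graph`.
#' @param include_ref add all REF_PRIMARY segments unconditionally
#'   (default `FALSE`).
#' @return character vector of segment ids.
#' @export
core_segments <- function(usage, g, include_ref = FALSE) {
  used_all <- rownames(usage)[rowSums(usage) == ncol(usage)]
  if (include_ref)
    used_all <- union(used_all,
                      g$segments[origin_class == "REF_PRIMARY", id])
  used_all
}

#' Classify genes as core / fragmented / absent
#'
#' The covered fraction of a gene is the share of its (merged) coding-exon
#' bases that intersect the stable-coordinate intervals of core REF_PRIMARY
#' segments.  A gene is `core` when the fraction exceeds 0.95 (strictly,
#' "over 95%"), `absent` at exactly 0, `fragmented` otherwise.
#'
#' @param annotation a `gene_annotation` from [load_annotation()].
#' @param core character vector of core segment ids (see [core_segments()]).
#' @param g the `pan_graph`.
#' @param mode `"base"` (default; base-level intersection) or
#'   `"contained"` (only exons fully contained in core segments count).
#' @param core_threshold fraction above which a gene is core (default 0.95).
#' @return data.table `gene_id`, `exon_bp`, `covered_bp`,
#'   `covered_fraction`, `class_call`; class counts and shares attached as
#'   attribute `summary`.
#' @export
classify_genes <- function(annotation, core, g,
                           mode = c("base", "contained"),
                           core_threshold = 0.95) {
  mode <- match.arg(mode)
  genes <- annotation$genes
  exons <- copy(annotation$exons)

  ref <- ref_index(g)[id %in% core]
  unknown <- setdiff(unique(exons$chrom), unique(g$segments$stable_name))
  if (length(unknown) > 0L)
    stop("gene annotation on unknown stable sequence(s): ",
         paste(unknown, collapse = ", "))

  exons[, covered := 0L]
  for (cn in unique(exons$chrom)) {
    core_ir <- IRanges::reduce(with(ref[stable_name == cn],
      IRanges::IRanges(start = stable_offset + 1L,
                       end = stable_offset + length_bp)))
    idx <- which(exons$chrom == cn)
    ex_ir <- IRanges::IRanges(start = exons$start[idx] + 1L,
                              end = exons$end[idx])
    if (mode == "base") {
      ov <- IRanges::findOverlaps(ex_ir, core_ir)
      if (length(ov) > 0L) {
        w <- IRanges::width(IRanges::pintersect(
          ex_ir[S4Vectors::queryHits(ov)], core_ir[S4Vectors::subjectHits(ov)]))
        cov <- tapply(w, S4Vectors::queryHits(ov), sum)
        exons$covered[idx[as.integer(names(cov))]] <- as.integer(cov)
      }
    } else {
      contained <- IRanges::overlapsAny(ex_ir, core_ir, type = "within")
      exons$covered[idx[contained]] <- IRanges::width(ex_ir)[contained]
    }
  }

  per_gene <- exons[, .(covered_bp = sum(covered),
                        exon_bp = sum(end - start)), by = gene_id]
  out <- merge(genes[, .(gene_id)], per_gene, by = "gene_id", all.x = TRUE)
  out[is.na(exon_bp), `:=`(exon_bp = 0L, covered_bp = 0L)]
  out[, covered_fraction := ifelse(exon_bp > 0, covered_bp / exon_bp, 0)]
  out[, class_call := fifelse(covered_fraction > core_threshold, "core",
                       fifelse(covered_fraction == 0, "absent", "fragmented"))]
  setorder(out, gene_id)

  smry <- out[, .N, by = class_call]
  smry[, share := N / sum(N)]
  setattr(out, "summary", smry[])
  out[]
}
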