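## Annotation of reference-anchored SV call sets: pLI loss-of-function LOD
## scores, repeat-overlap fractions, cross-sample merging into distinct SVs
## and singleton counts.

SV_TYPES <- c("DEL", "INS", "DUP", "INV", "TRA")

#' Read an SV table from TSV
#'
#' Expected columns: `chrom`, `start`, `end` (0-based half-open; for INS
#' `end = start + 1` with the insert length in `length_bp`), `type`
#' (DEL/INS/DUP/INV/TRA), `length_bp`, `sample_id`; TRA rows additionally
#' carry `chrom2`, `pos2`.
#'
#' @param path TSV file.
#' @return data.table of SV records.
#' @export
read_sv_tsv <- function(path) {
  sv <- fread(path, sep = "\t")
  req <- c("chrom", "start", "end", "type", "length_bp", "sample_id")
  miss <- setdiff(req, names(sv))
  if (length(miss) > 0L)
    stop("SV table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(sv$type %in% SV_TYPES))
    stop("unknown SV type(s): ",
         paste(setdiff(unique(sv$type), SV_TYPES), collapse = ", "))
  if (any(sv$start >= sv$end)) stop("SV with start >= end")
  if (any(sv$length_bp <= 0)) stop("SV with non-positive length")
  sv
}

#' Read SVs from a VCF with SVTYPE/SVLEN/END INFO keys
#'
#' @param path uncompressed VCF file.
#' @param sample_id sample to assign the records to (default: first sample
#'   column, or the file name).
#' @return data.table in the layout of [read_sv_tsv()].
#' @export
read_sv_vcf <- function(path, sample_id = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (is.null(sample_id)) {
    sm <- colnames(vcf)
    sample_id <- if (length(sm) > 0L) sm[1L] else basename(path)
  }
  svtype <- as.character(info$SVTYPE)
  svlen <- abs(as.numeric(sapply(info$SVLEN, function(x)
    if (length(x) == 0L) NA_real_ else x[[1L]])))
  end1 <- as.numeric(sapply(info$END, function(x)
    if (length(x) == 0L) NA_real_ else x[[1L]]))
  pos1 <- GenomicRanges::start(rr)
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    start = pos1 - 1L,
    end = as.integer(ifelse(svtype == "INS", pos1, end1)),
    type = svtype,
    length_bp = as.integer(ifelse(is.na(svlen),
                                  pmax(end1 - pos1 + 1L, 1L), svlen)),
    sample_id = sample_id
  )
  if ("CHR2" %in% names(info))
    dt[, chrom2 := as.character(info$CHR2)]
  if ("POS2" %in% names(info))
    dt[, pos2 := as.integer(sapply(info$POS2, function(x)
      if (length(x) == 0L) NA_integer_ else x[[1L]]))]
  dt
}

#' Read a two-column pLI table
#'
#' @param path TSV with columns `gene_id`, `pli`.
#' @return data.table validated to pLI in \[0, 1\].
#' @export
read_pli <- function(path) {
  p <- fread(path, sep = "\t")
  if (!all(c("gene_id", "pli") %in% names(p)))
    stop("pLI table needs columns gene_id, pli")
  if (any(p$pli < 0 | p$pli > 1))
    stop("pLI scores outside [0, 1]")
  p
}

#' pLI loss-of-function LOD score for SVs
#'
#' For each SV, the LOD is the sum over overlapping genes of
#' `log10(p' / (1 - p'))` with `p' = clamp(pli, eps, 1 - eps)`.  SVs that
#' overlap no scored gene get `NA` (reported distinctly from 0).
#'
#' @param svs SV data.table (see [read_sv_tsv()]).
#' @param genes data.table of gene intervals: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open); e.g. `annotation$genes` renamed from
#'   `gene_start`/`gene_end`.
#' @param pli data.table from [read_pli()].
#' @param eps clamp in (0, 0.5) keeping the LOD finite for pLI of 0 or 1.
#' @return `svs` with a `lod` column added (copy).
#' @export
pli_lod <- function(svs, genes, pli, eps = 1e-16) {
  stopifnot(eps > 0, eps < 0.5)
  if (any(pli$pli < 0 | pli$pli > 1)) stop("pLI scores outside [0, 1]")
  gn <- merge(genes, pli, by = "gene_id")
  gn[, lod1 := log10(pmin(pmax(pli, eps), 1 - eps) /
                       (1 - pmin(pmax(pli, eps), 1 - eps)))]
  out <- copy(svs)
  out[, lod := {
    vapply(seq_len(.N), function(i) {
      hit <- gn[chrom == out$chrom[i] & start < out$end[i] &
                  end > out$start[i]]
      if (nrow(hit) == 0L) NA_real_ else sum(hit$lod1)
    }, numeric(1))
  }]
  out[]
}

## GRanges of SV "regions" for overlap work; TRA uses both breakend loci
## padded +/- pad bp.
sv_regions <- function(svs, pad_tra = 100L) {
  reg <- svs[type != "TRA", .(idx = .I[type != "TRA"], chrom, start, end)]
  tra <- svs[type == "TRA"]
  if (nrow(tra) > 0L) {
    i_tra <- which(svs$type == "TRA")
    reg <- rbind(reg,
      data.table(idx = i_tra, chrom = tra$chrom,
                 start = pmax(tra$start - pad_tra, 0L),
                 end = tra$start + pad_tra),
      if (!is.null(tra$chrom2))
        data.table(idx = i_tra, chrom = tra$chrom2,
                   start = pmax(tra$pos2 - pad_tra, 0L),
                   end = tra$pos2 + pad_tra))
  }
  reg
}

#' Fraction of distinct SVs overlapping repeats, per type
#'
#' Repeat intervals are merged (strand-ignored) before overlap; an SV
#' counts once however many repeats it touches.  TRA regions are both
#' breakend loci padded by `pad_tra`.
#'
#' @param svs SV data.table (distinct calls).
#' @param repeats data.table `chrom`, `start`, `end` (0-based half-open),
#'   e.g. from [read_bed()].
#' @param pad_tra padding around TRA breakends (default 100 bp).
#' @return data.table `type`, `n`, `n_overlap`, `fraction`.
#' @export
repeat_overlap <- function(svs, repeats, pad_tra = 100L) {
  rpt_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    repeats$chrom,
    IRanges::IRanges(start = repeats$start + 1L, end = repeats$end)))
  reg <- sv_regions(svs, pad_tra)
  reg_gr <- GenomicRanges::GRanges(
    reg$chrom, IRanges::IRanges(start = reg$start + 1L, end = reg$end))
  hit_idx <- unique(reg$idx[IRanges::overlapsAny(reg_gr, rpt_gr)])
  dt <- copy(svs)[, hit := .I %in% hit_idx]
  out <- dt[, .(n = .N, n_overlap = sum(hit)), by = type]
  out[, fraction := n_overlap / n]
  setorder(out, type)
  out[]
}

#' Merge per-sample SV calls into distinct SVs
#'
#' Two same-type calls merge when their reciprocal overlap is at least
#' `reciprocal` and both breakpoint shifts are at most `max_shift`;
#' clusters are transitive closures, so merging is order-independent.  A
#' distinct SV takes the component-wise interval hull and the union of
#' carrier samples.
#'
#' @param svs concatenated per-sample SV data.table.
#' @param reciprocal minimum reciprocal overlap (default 0.8).
#' @param max_shift maximum breakpoint shift in bp (default 1000).
#' @return data.table `chrom`, `start`, `end`, `type`, `length_bp`,
#'   `carriers` (list), `n_carriers`, `n_calls`.
#' @export
merge_distinct <- function(svs, reciprocal = 0.8, max_shift = 1000) {
  sv <- copy(svs)
  setorder(sv, type, chrom, start, end, sample_id)
  n <- nrow(sv)
  if (n == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), type = character(),
                      length_bp = integer(), carriers = list(),
                      n_carriers = integer(), n_calls = integer()))

  gr <- GenomicRanges::GRanges(
    paste(sv$type, sv$chrom, sep = ":"),
    IRanges::IRanges(start = sv$start + 1L, end = sv$end))
  ov <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  keep <- qi < si
  qi <- qi[keep]; si <- si[keep]
  if (length(qi) > 0L) {
    inter <- pmin(sv$end[qi], sv$end[si]) - pmax(sv$start[qi], sv$start[si])
    rec_ok <- inter >= reciprocal * (sv$end[qi] - sv$start[qi]) &
      inter >= reciprocal * (sv$end[si] - sv$start[si])
    shift_ok <- abs(sv$start[qi] - sv$start[si]) <= max_shift &
      abs(sv$end[qi] - sv$end[si]) <= max_shift
    qi <- qi[rec_ok & shift_ok]; si <- si[rec_ok & shift_ok]
  }
  comp <- uf_components(n, qi, si)
  sv[, cluster := comp]
  out <- sv[, .(chrom = chrom[1L], start = min(start), end = max(end),
                type = type[1L], length_bp = max(length_bp),
                carriers = list(sort(unique(sample_id))),
                n_carriers = length(unique(sample_id)), n_calls = .N),
            by = cluster][, cluster := NULL]
  setorder(out, type, chrom, start, end)
  out[]
}

#' Total and singleton SV counts per sample and type
#'
#' A distinct SV is a singleton when exactly one sample carries it.
#'
#' @param distinct output of [merge_distinct()].
#' @param samples optional character vector fixing sample order (samples
#'   carrying nothing still get a row).
#' @return data.table `sample_id`, `type`, `n_total`, `n_singleton`.
#' @export
singleton_counts <- function(distinct, samples = NULL) {
  long <- distinct[, .(sample_id = carriers[[1L]],
                       singleton = n_carriers == 1L),
                   by = .(rid = seq_len(nrow(distinct)), type)]
  out <- long[, .(n_total = .N, n_singleton = sum(singleton)),
              by = .(sample_id, type)]
  if (!is.null(samples)) {
    grid <- CJ(sample_id = samples, type = sort(unique(distinct$type)))
    out <- merge(grid, out, by = c("sample_id", "type"), all.x = TRUE)
    out[is.na(n_total), `:=`(n_total = 0L, n_singleton = 0L)]
  }
  setorder(out, sample_id, type)
  out[]
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file.
#' @return data.table `chrom`, `start`, `end` (0-based half-open; BED
#'   native convention), plus `name` when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  dt <- data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) dt[, name := as.character(nm)]
  dt
}
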