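## Differential methylation over CpG islands from per-read log-likelihood
## ratios: per-position sample medians, Kruskal-Wallis across samples,
## Benjamini-Hochberg FDR, per-sample island states, clustering matrix and
## TSS-distance comparison.

#' Read per-read CpG methylation calls
#'
#' Nanopolish-style TSV with columns `sample_id`, `chrom`, `position`
#' (0-based forward-strand C of the CpG dyad), `read_id`,
#' `log_lik_ratio` (natural-log methylated over unmethylated).
#'
#' @param paths one or more TSV files (concatenated).
#' @return data.table of calls.
#' @export
read_meth_calls <- function(paths) {
  calls <- rbindlist(lapply(paths, fread, sep = "\t"))
  req <- c("sample_id", "chrom", "position", "read_id", "log_lik_ratio")
  miss <- setdiff(req, names(calls))
  if (length(miss) > 0L)
    stop("methylation call table missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(calls$log_lik_ratio)))
    stop("non-finite log-likelihood ratios")
  calls
}

#' Aggregate per-read calls to per-position sample medians
#'
#' @param calls data.table from [read_meth_calls()].
#' @param min_reads positions covered by fewer reads in a sample are
#'   dropped for that sample (default 5).
#' @return data.table `sample_id`, `chrom`, `position`, `n_reads`,
#'   `median_llr`.
#' @export
aggregate_sites <- function(calls, min_reads = 5L) {
  out <- calls[, .(n_reads = .N, median_llr = median(log_lik_ratio)),
               by = .(sample_id, chrom, position)]
  out <- out[n_reads >= min_reads]
  setorder(out, chrom, position, sample_id)
  out[]
}

#' Kruskal-Wallis rank test with tie correction
#'
#' The chi-squared approximation with tie correction; when every
#' observation is tied (no variation at all) the statistic is defined as
#' H = 0 with p = 1.
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @return list `H`, `df`, `p_value`, `n`, `k`.
#' @export
kw_test <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.factor(as.character(groups))
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) stop("Kruskal-Wallis needs at least 2 groups")
  r <- rank(values)
  rs <- tapply(r, groups, sum)
  ns <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) return(list(H = 0, df = k - 1L, p_value = 1, n = n, k = k))
  h <- h / corr
  list(H = h, df = k - 1L, p_value = pchisq(h, k - 1L, lower.tail = FALSE),
       n = n, k = k)
}

#' Per-sample methylation state from an island median LLR
#'
#' `methylated` at median LLR >= 1, `unmethylated` at <= -1, `ambiguous`
#' in the open band between (the heatmap ambiguity band).
#'
#' @param m numeric island median LLRs.
#' @return character vector of states.
#' @export
llr_state <- function(m) {
  fifelse(m >= 1, "methylated", fifelse(m <= -1, "unmethylated", "ambiguous"))
}

#' Test CpG islands for differential methylation across samples
#'
#' For each island, the site medians of every sample contributing at least
#' `min_sites` positions are compared across samples with the
#' Kruskal-Wallis test; islands with fewer than `min_samples` such samples
#' are skipped (reason recorded).  P-values of tested islands are adjusted
#' with [bh_adjust()].
#'
#' @param sites data.table from [aggregate_sites()].
#' @param islands data.table `chrom`, `start`, `end` (0-based half-open),
#'   optionally `name`.
#' @param min_sites minimum site medians per sample per island (default 3).
#' @param min_samples minimum contributing samples per island (default 4).
#' @param alpha FDR level for the `significant` flag (default 0.01).
#' @return a `meth_tests` list: `tests` (data.table: island coords, n
#'   samples/sites, `H`, `p_value`, `q_value`, `significant`),
#'   `sample_medians` (data.table island x sample island-median LLR and
#'   state), `skipped` (islands with reason codes).
#' @export
test_islands <- function(sites, islands, min_sites = 3L, min_samples = 4L,
                         alpha = 0.01) {
  isl <- copy(islands)
  if (!"name" %in% names(isl))
    isl[, name := paste0(chrom, ":", start, "-", end)]
  isl[, island_idx := .I]

  st <- copy(sites)
  ov <- isl[st, on = .(chrom, start <= position, end > position),
            .(island_idx = island_idx, sample_id = i.sample_id,
              position = i.position, median_llr = i.median_llr),
            nomatch = NULL]

  ## samples contributing >= min_sites site medians, per island
  cnt <- ov[, .N, by = .(island_idx, sample_id)]
  eligible <- cnt[N >= min_sites, .(island_idx, sample_id)]
  n_samp <- eligible[, .(n_eligible = .N), by = island_idx]

  need <- max(min_samples, 2L)
  tested_ids <- n_samp[n_eligible >= need, island_idx]
  skipped <- isl[, .(island_idx)]
  skipped <- merge(skipped, n_samp, by = "island_idx", all.x = TRUE)
  skipped[is.na(n_eligible), n_eligible := 0L]
  skipped <- skipped[!(island_idx %in% tested_ids)]
  skipped[, reason := fifelse(n_eligible < 2L, "fewer_than_2_samples",
                              "below_min_samples")]
  skipped[, n_eligible := NULL]

  ov2 <- ov[eligible, on = c("island_idx", "sample_id"), nomatch = NULL]
  ov2 <- ov2[island_idx %in% tested_ids]

  tests <- ov2[, {
    kw <- kw_test(median_llr, sample_id)
    .(n_samples = uniqueN(sample_id), n_sites = .N, H = kw$H,
      p_value = kw$p_value)
  }, by = island_idx]
  med <- ov2[, .(island_median_llr = median(median_llr)),
             by = .(island_idx, sample_id)]
  if (nrow(tests) > 0L) {
    tests[, q_value := bh_adjust(p_value)]
    tests[, significant := q_value <= alpha]
  } else {
    tests <- data.table(island_idx = integer(), n_samples = integer(),
                        n_sites = integer(), H = numeric(),
                        p_value = numeric(), q_value = numeric(),
                        significant = logical())
  }
  tests <- merge(isl[, .(island_idx, chrom, start, end, name)], tests,
                 by = "island_idx")
  setorder(tests, chrom, start)

  if (nrow(med) > 0L) {
    med <- merge(isl[, .(island_idx, chrom, start, end, name)], med,
                 by = "island_idx")
    med[, state := llr_state(island_median_llr)]
    setorder(med, chrom, start, sample_id)
  }
  if (nrow(skipped) > 0L)
    skipped <- merge(isl[, .(island_idx, chrom, start, end, name)], skipped,
                     by = "island_idx")
  structure(list(tests = tests[], sample_medians = med,
                 skipped = skipped, alpha = alpha),
            class = "meth_tests")
}

#' @export
print.meth_tests <- function(x, ...) {
  cat("meth_tests:", nrow(x$tests), "islands tested,",
      sum(x$tests$significant), "significant at FDR", x$alpha, ";",
      nrow(x$skipped), "skipped\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_(i) = min over j >= i of m * p_(j) / j`, clipped at 1;
#' order-preserving and idempotent on already-adjusted inputs.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(rev(cummin(rev(m * p[o] / seq_len(m)))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Distance of islands to the closest gene TSS
#'
#' Distance is 0 when a TSS lies inside the island interval, otherwise the
#' gap to the nearer island edge.  When significance flags are present the
#' significant and non-significant distance distributions are compared
#' with a two-sided rank-sum test.
#'
#' @param tests the `tests` data.table from [test_islands()] (or any table
#'   with `chrom`, `start`, `end`, optionally `significant`).
#' @param genes data.table with `chrom` and 0-based `tss` positions (e.g.
#'   `annotation$genes`).
#' @return data.table of per-island distances; when applicable a list
#'   summary (`median_significant`, `median_nonsignificant`,
#'   `rank_sum_p`) is attached as attribute `comparison`.
#' @export
tss_distance_summary <- function(tests, genes) {
  out <- copy(tests)
  out[, tss_distance := {
    vapply(seq_len(.N), function(i) {
      tss_i <- genes$tss[genes$chrom == chrom[i]]
      if (length(tss_i) == 0L) return(NA_real_)
      inside <- tss_i >= start[i] & tss_i < end[i]
      if (any(inside)) 0
      else min(pmax(start[i] - tss_i, tss_i - (end[i] - 1L)))
    }, numeric(1))
  }]
  if ("significant" %in% names(out) && any(out$significant) &&
      any(!out$significant)) {
    dsig <- out[significant == TRUE, tss_distance]
    dnon <- out[significant == FALSE, tss_distance]
    cmp <- list(median_significant = median(dsig, na.rm = TRUE),
                median_nonsignificant = median(dnon, na.rm = TRUE),
                rank_sum_p = wilcox.test(dsig, dnon, exact = FALSE)$p.value)
    setattr(out, "comparison", cmp)
  }
  out[]
}

#' Significant-island report and clustering matrix
#'
#' @param meth a `meth_tests` from [test_islands()].
#' @param alpha FDR level (default the one used for testing).
#' @return list with `significant` (tests at `q <= alpha`) and `matrix`
#'   (islands x samples of island median LLR over significant islands;
#'   values conventionally displayed on -3..3 with |llr| < 1 ambiguous).
#' @export
dmr_report <- function(meth, alpha = meth$alpha) {
  sig <- meth$tests[q_value <= alpha]
  if (nrow(sig) == 0L)
    return(list(significant = sig, matrix = matrix(numeric(0), 0, 0)))
  med <- meth$sample_medians[island_idx %in% sig$island_idx]
  wide <- dcast(med, island_idx ~ sample_id, value.var = "island_median_llr")
  m <- as.matrix(wide[, -1L])
  rownames(m) <- meth$tests[match(wide$island_idx, island_idx), name]
  list(significant = sig, matrix = m)
}
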