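## Simulated per-read CpG methylation calls: a two-component LLR mixture
## (Normal(+mu, sigma) with probability = the sample's methylation rate at
## the site, else Normal(-mu, sigma)), with planted differentially
## methylated islands between two sample groups and shared rate profiles
## (plus small noise) within sibling pairs.

#' Simulate per-read methylation calls over CpG islands
#'
#' Non-DMR islands share one base rate across all samples; DMR islands
#' offset the two halves of the panel by `meth_dmr_delta` (sibling pairs
#' always fall in the same group).  Each sibling pair shares a
#' lineage-level rate jitter so sibling profiles are more alike than
#' unrelated samples.
#'
#' @param cfg a [sim_config()].
#' @param islands data.table `chrom`, `start`, `end`, `name`, `dmr`
#'   (e.g. from [simulate_annotation()]); when `NULL` a standalone island
#'   grid is generated.
#' @return list with `calls` (data.table: sample_id, chrom, position,
#'   read_id, log_lik_ratio), `islands`, and `truth` (per-island,
#'   per-sample true rates and DMR flags).
#' @export
simulate_meth <- function(cfg, islands = NULL) {
  set.seed(derive_seed(cfg$seed, 4L))
  if (is.null(islands)) {
    n <- cfg$meth_n_islands
    dmr <- rep(FALSE, n)
    if (cfg$meth_n_dmr > 0L)
      dmr[sort(sample(n, min(cfg$meth_n_dmr, n)))] <- TRUE
    islands <- data.table(chrom = "HdrR_1",
                          start = (seq_len(n) - 1L) * 1500L,
                          end = (seq_len(n) - 1L) * 1500L + 500L,
                          dmr = dmr,
                          name = sprintf("cgi%05d", seq_len(n)))
  }
  samples <- cfg$samples
  n_s <- length(samples)
  ## sibling pairs are the leading consecutive pairs; lineages group them
  lineage <- c(rep(seq_len(cfg$sib_pairs), each = 2L),
               seq(cfg$sib_pairs + 1L,
                   length.out = n_s - 2L * cfg$sib_pairs))
  ## DMR group split in half by whole lineages so sibs share a group
  lin_sizes <- tabulate(lineage)
  grp_of_lin <- ifelse(cumsum(lin_sizes) <= n_s / 2, 1L, 2L)
  group <- grp_of_lin[lineage]

  n_isl <- nrow(islands)
  n_lin <- max(lineage)

  ## per-island base rates and per-lineage jitter
  base <- sample(cfg$meth_base_rates, n_isl, replace = TRUE)
  lin_jit <- matrix(rnorm(n_isl * n_lin, 0, cfg$meth_lineage_sd),
                    n_isl, n_lin)

  lo <- (1 - cfg$meth_dmr_delta) / 2
  hi <- 1 - lo
  ## DMR rates: in the "lineage" design each lineage draws its own rate
  ## (lo or hi) at a DMR island — line-level, heritable methylation, the
  ## structure that makes sibling profiles duplicates; the "group" design
  ## offsets two fixed halves of the panel (the classical two-group power
  ## setting)
  dmr_rate <- matrix(0, n_isl, n_s)
  if (cfg$meth_dmr_design == "lineage") {
    lin_rate <- matrix(sample(c(lo, hi), n_isl * n_lin, replace = TRUE),
                       n_isl, n_lin)
    uniform <- which(islands$dmr &
                       apply(lin_rate, 1L, function(x)
                         length(unique(x)) == 1L))
    for (i in uniform)  ## a DMR island must actually differ between lines
      lin_rate[i, sample.int(n_lin, 1L)] <-
        if (lin_rate[i, 1L] == lo) hi else lo
    dmr_rate <- lin_rate[, lineage, drop = FALSE]
  } else {
    dmr_rate <- matrix(rep(ifelse(group == 1L, lo, hi), each = n_isl),
                       n_isl, n_s)
  }
  rate <- matrix(0, n_isl, n_s, dimnames = list(islands$name, samples))
  for (s in seq_len(n_s)) {
    r <- ifelse(islands$dmr, dmr_rate[, s], base)
    r <- r + lin_jit[, lineage[s]] + rnorm(n_isl, 0, cfg$meth_sib_noise)
    rate[, s] <- pmin(pmax(r, 0.02), 0.98)
  }

  n_sites <- cfg$meth_sites_per_island
  n_reads <- cfg$meth_reads_per_site
  site_off <- round(seq(10, 480, length.out = n_sites))

  grid <- CJ(island_idx = seq_len(n_isl), site = seq_len(n_sites),
             sample_idx = seq_len(n_s), read = seq_len(n_reads))
  grid[, position := islands$start[island_idx] + site_off[site]]
  grid[, chrom := islands$chrom[island_idx]]
  grid[, sample_id := samples[sample_idx]]
  p <- rate[cbind(grid$island_idx, grid$sample_idx)]
  meth <- runif(nrow(grid)) < p
  grid[, log_lik_ratio := rnorm(.N, ifelse(meth, cfg$meth_mu, -cfg$meth_mu),
                                cfg$meth_sigma)]
  grid[, read_id := sprintf("r%d_%d", island_idx, read)]
  calls <- grid[, .(sample_id, chrom, position, read_id, log_lik_ratio)]

  truth <- data.table(islands[, .(name, chrom, start, end, dmr)],
                      group_lo = lo, group_hi = hi)
  list(calls = calls, islands = islands,
       truth = list(islands = truth, rates = rate, group = group,
                    lineage = lineage))
}
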