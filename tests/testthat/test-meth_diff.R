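mk_calls <- function(llrs, sample = "s1", pos = 100L) {
  data.table(sample_id = sample, chrom = "chr1", position = pos,
             read_id = sprintf("r%d", seq_along(llrs)),
             log_lik_ratio = llrs)
}

test_that("aggregate_sites takes medians and applies the read filter", {
  calls <- mk_calls(c(2, 3, -1))
  agg <- aggregate_sites(calls, min_reads = 1L)
  expect_equal(agg$median_llr, 2)
  expect_equal(agg$n_reads, 3L)
  ## 4 reads at min_reads = 5 drops the position
  expect_equal(nrow(aggregate_sites(mk_calls(1:4), min_reads = 5L)), 0L)
  ## per-sample, per-position grouping
  calls2 <- rbind(mk_calls(c(1, 2, 3)), mk_calls(c(-5, -6, -7), "s2"))
  agg2 <- aggregate_sites(calls2, min_reads = 3L)
  expect_equal(agg2[sample_id == "s2", median_llr], -6)
})

test_that("median llr sign tracks a strongly methylated mixture", {
  ## rate 0.8, mu 2.5, sigma 1, 30 reads: median above 0 in >= 99% of sims
  set.seed(77)
  hits <- replicate(1000, {
    meth <- runif(30) < 0.8
    median(rnorm(30, ifelse(meth, 2.5, -2.5), 1)) > 0
  })
  expect_gte(mean(hits), 0.99)
})

test_that("kw_test matches kruskal.test and defines the degenerate case", {
  v <- c(1, 2, 3, 4, 5, 6)
  gl <- rep(c("a", "b"), each = 3)
  got <- kw_test(v, gl)
  ref <- kruskal.test(v, factor(gl))
  expect_equal(got$H, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
  ## ties
  vt <- c(1, 1, 2, 2, 3, 3, 3)
  gt <- c("a", "a", "b", "b", "a", "b", "b")
  got_t <- kw_test(vt, gt)
  ref_t <- kruskal.test(vt, factor(gt))
  expect_equal(got_t$H, unname(ref_t$statistic))
  ## all observations tied: H = 0, p = 1 (kruskal.test returns NaN here)
  deg <- kw_test(rep(1, 6), gl)
  expect_equal(deg$H, 0)
  expect_equal(deg$p_value, 1)
  expect_error(kw_test(1:3, rep("a", 3)), "2 groups")
})

test_that("test_islands scores islands and states follow the llr band", {
  islands <- data.table(chrom = "chr1", start = 0L, end = 1000L,
                        name = "isl1")
  sites <- rbindlist(lapply(1:4, function(s)
    data.table(sample_id = paste0("s", s), chrom = "chr1",
               position = c(10L, 20L, 30L), n_reads = 10L,
               median_llr = c(1, 2, 3) + (s == 4) * 3)))
  mt <- test_islands(sites, islands, min_sites = 3, min_samples = 4)
  expect_equal(nrow(mt$tests), 1L)
  ref <- kruskal.test(sites$median_llr, factor(sites$sample_id))
  expect_equal(mt$tests$H, unname(ref$statistic))
  expect_equal(mt$tests$p_value, ref$p.value)
  st <- mt$sample_medians
  expect_equal(st[sample_id == "s1", state], "methylated")   ## median 2
  expect_equal(st[sample_id == "s4", state], "methylated")
  ## identical vectors across samples -> H = 0, p = 1
  sites_eq <- copy(sites)[, median_llr := rep(c(1, 2, 3), 4)]
  mt_eq <- test_islands(sites_eq, islands, min_sites = 3, min_samples = 4)
  expect_equal(mt_eq$tests$H, 0)
  expect_equal(mt_eq$tests$p_value, 1)
  ## ambiguity band boundaries
  expect_equal(llr_state(c(0.5, -0.5, 1, -1, 2.5)),
               c("ambiguous", "ambiguous", "methylated", "unmethylated",
                 "methylated"))
})

test_that("islands below coverage thresholds are skipped with reasons", {
  islands <- data.table(chrom = "chr1", start = c(0L, 2000L),
                        end = c(1000L, 3000L), name = c("a", "b"))
  ## island b: only 1 sample with enough sites
  sites <- rbind(
    rbindlist(lapply(1:4, function(s)
      data.table(sample_id = paste0("s", s), chrom = "chr1",
                 position = c(10L, 20L, 30L), n_reads = 10L,
                 median_llr = rnorm(3)))),
    data.table(sample_id = "s1", chrom = "chr1",
               position = c(2010L, 2020L, 2030L), n_reads = 10L,
               median_llr = rnorm(3)))
  mt <- test_islands(sites, islands, min_sites = 3, min_samples = 4)
  expect_equal(mt$tests$name, "a")
  expect_equal(mt$skipped$name, "b")
  expect_equal(mt$skipped$reason, "fewer_than_2_samples")
})

test_that("bh_adjust reproduces the step-up closed form", {
  p <- c(0.001, 0.008, 0.039, 0.041)
  expect_equal(bh_adjust(p), c(0.004, 0.016, 0.041, 0.041))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (i in 1:20) {
    pv <- runif(sample(1:40, 1))
    q <- bh_adjust(pv)
    expect_equal(q, oracle_bh(pv))
    expect_equal(q, p.adjust(pv, method = "BH"))
    ## order-preserving: q is monotone along sorted p
    expect_true(all(diff(q[order(pv)]) >= -1e-12))
    ## the step-up monotonisation itself is idempotent: re-running the
    ## cummin over already-monotone q/rank ratios changes nothing
    expect_equal(rev(cummin(rev(sort(q)))), sort(q))
  }
})

test_that("tss distances are zero inside islands and gap otherwise", {
  tests <- data.table(chrom = "chr1", start = 1000L, end = 2000L,
                      name = "i1")
  genes_in <- data.table(chrom = "chr1", tss = 1500L)
  genes_out <- data.table(chrom = "chr1", tss = 2500L)
  genes_left <- data.table(chrom = "chr1", tss = 400L)
  expect_equal(tss_distance_summary(tests, genes_in)$tss_distance, 0)
  expect_equal(tss_distance_summary(tests, genes_out)$tss_distance, 501)
  expect_equal(tss_distance_summary(tests, genes_left)$tss_distance, 600)
})

test_that("planted TSS-proximal DMRs shrink the significant-set distance", {
  sh <- shared_sim()
  genes <- sh$ann$genes[, .(chrom, tss)]
  for (seed in c(101L, 102L, 103L)) {
    meth <- simulate_meth(tiny_cfg(seed = seed), sh$ann$islands)
    mt <- test_islands(aggregate_sites(meth$calls, 5L), sh$ann$islands,
                       alpha = 0.01)
    tssd <- tss_distance_summary(mt$tests, genes)
    cmp <- attr(tssd, "comparison")
    expect_lt(cmp$median_significant, cmp$median_nonsignificant)
  }
})

test_that("dmr_report returns significant islands and a cluster matrix", {
  cfg <- tiny_cfg()
  sh <- shared_sim()
  meth <- simulate_meth(cfg, sh$ann$islands)
  sites <- aggregate_sites(meth$calls, 5L)
  mt <- test_islands(sites, sh$ann$islands, alpha = 0.01)
  rep_ <- dmr_report(mt)
  expect_equal(nrow(rep_$significant), sum(mt$tests$q_value <= 0.01))
  expect_equal(ncol(rep_$matrix), length(cfg$samples))
  expect_equal(nrow(rep_$matrix), nrow(rep_$significant))
  ## all planted DMRs are recovered at this effect size
  planted <- sh$ann$islands[dmr == TRUE, name]
  expect_true(all(planted %in% rep_$significant$name))
  ## no islands significant -> empty report
  mt0 <- mt
  mt0$tests <- copy(mt$tests)[, q_value := 1]
  expect_equal(nrow(dmr_report(mt0)$significant), 0L)
})
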