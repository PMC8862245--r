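mk_genes <- function() {
  data.table(gene_id = c("g1", "g2", "g3"),
             chrom = "chr1",
             start = c(1000L, 5000L, 9000L),
             end = c(2000L, 6000L, 10000L))
}

test_that("pli_lod matches the closed form and flags unscored SVs", {
  genes <- mk_genes()
  pli <- data.table(gene_id = c("g1", "g2", "g3"), pli = c(0.5, 0.9, 0.5))
  svs <- data.table(chrom = "chr1",
                    start = c(1500L, 5200L, 1500L, 20000L),
                    end = c(1600L, 5300L, 6000L, 20100L),
                    type = "DEL", length_bp = 100L, sample_id = "s1")
  out <- pli_lod(svs, genes, pli)
  expect_equal(out$lod[1], 0)                      ## pLI 0.5: even odds
  expect_equal(out$lod[2], log10(0.9 / 0.1))       ## ~0.954
  ## additivity over two overlapped genes (0.5 contributes 0)
  expect_equal(out$lod[3], log10(9))
  expect_true(is.na(out$lod[4]))                   ## no gene: NA, not 0
})

test_that("clamping keeps pLI of 0 and 1 finite and eps is validated", {
  genes <- mk_genes()[1]
  sv <- data.table(chrom = "chr1", start = 1500L, end = 1600L,
                   type = "DEL", length_bp = 100L, sample_id = "s1")
  lod1 <- pli_lod(sv, genes, data.table(gene_id = "g1", pli = 1))$lod
  lod0 <- pli_lod(sv, genes, data.table(gene_id = "g1", pli = 0))$lod
  expect_true(is.finite(lod1) && lod1 > 10)
  ## antisymmetric up to one ulp of the 1 - eps clamp
  expect_equal(lod0, -lod1, tolerance = 1e-2)
  ## eps = 1e-6 reproduces a bounded magnitude
  lod_e <- pli_lod(sv, genes, data.table(gene_id = "g1", pli = 1),
                   eps = 1e-6)$lod
  expect_equal(lod_e, log10((1 - 1e-6) / 1e-6))
  expect_error(pli_lod(sv, genes, data.table(gene_id = "g1", pli = 2)),
               "\\[0, 1\\]")
  expect_error(pli_lod(sv, genes, data.table(gene_id = "g1", pli = 0.5),
                       eps = 0.7))
})

test_that("repeat_overlap respects half-open boundaries and merging", {
  svs <- data.table(chrom = "chr1",
                    start = c(100L, 100L), end = c(200L, 200L),
                    type = c("DEL", "INV"), length_bp = 100L,
                    sample_id = "s1")
  rpt_in <- data.table(chrom = "chr1", start = 150L, end = 160L)
  rpt_out <- data.table(chrom = "chr1", start = 200L, end = 300L)
  expect_equal(repeat_overlap(svs, rpt_in)$fraction, c(1, 1))
  ## [100,200) vs [200,300): half-open means no overlap
  expect_equal(repeat_overlap(svs, rpt_out)$fraction, c(0, 0))
  ## invariance under splitting a repeat into adjacent pieces
  split_rpt <- data.table(chrom = "chr1", start = c(150L, 155L),
                          end = c(155L, 160L))
  expect_equal(repeat_overlap(svs, split_rpt), repeat_overlap(svs, rpt_in))
})

test_that("TRA regions are padded breakends", {
  tra <- data.table(chrom = "chr1", start = 1000L, end = 1001L,
                    type = "TRA", length_bp = 1L, sample_id = "s1",
                    chrom2 = "chr2", pos2 = 5000L)
  near_bnd2 <- data.table(chrom = "chr2", start = 4950L, end = 4960L)
  far <- data.table(chrom = "chr2", start = 6000L, end = 6100L)
  expect_equal(repeat_overlap(tra, near_bnd2)$fraction, 1)
  expect_equal(repeat_overlap(tra, far)$fraction, 0)
})

test_that("merge_distinct clusters by reciprocal overlap and shift", {
  base <- data.table(chrom = "chr1", type = "DEL", length_bp = 1000L)
  calls <- rbind(
    data.table(base, start = 1000L, end = 2000L, sample_id = sprintf("s%d", 1:9)),
    data.table(base, start = 5000L, end = 6000L, sample_id = "s1"),
    data.table(base, start = 5900L, end = 6900L, sample_id = "s2"))
  got <- merge_distinct(calls)
  expect_equal(nrow(got), 3L)   ## 10% overlap does not merge
  nine <- got[start == 1000L]
  expect_equal(nine$n_carriers, 9L)
  ## chain a~b, b~c collapses to one cluster (transitive closure)
  chain <- data.table(chrom = "chr1", type = "DEL", length_bp = 1000L,
                      start = c(1000L, 1400L, 1800L),
                      end = c(2000L, 2400L, 2800L),
                      sample_id = c("a", "b", "c"))
  cl <- merge_distinct(chain, reciprocal = 0.5, max_shift = 500)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$carriers[[1]], c("a", "b", "c"))
  ## idempotence: re-merging the merged set changes nothing
  re <- merge_distinct(cl[, .(chrom, start, end, type, length_bp,
                              sample_id = "merged")],
                       reciprocal = 0.5, max_shift = 500)
  expect_equal(re[, .(chrom, start, end, type)],
               cl[, .(chrom, start, end, type)])
  ## order independence
  perm <- merge_distinct(calls[sample(.N)])
  setkey(perm, chrom, start); setkey(got, chrom, start)
  expect_equal(perm[, .(start, end, n_carriers)],
               got[, .(start, end, n_carriers)])
})

test_that("same-type-only merging and singleton counting", {
  calls <- data.table(chrom = "chr1", start = 1000L, end = 2000L,
                      type = c("DEL", "DUP"), length_bp = 1000L,
                      sample_id = c("s1", "s2"))
  got <- merge_distinct(calls)
  expect_equal(nrow(got), 2L)  ## identical intervals, different types
  sc <- singleton_counts(got, samples = c("s1", "s2", "s3"))
  expect_equal(sc[sample_id == "s1" & type == "DEL", n_singleton], 1L)
  expect_equal(sc[sample_id == "s3", sum(n_total)], 0L)
  two <- merge_distinct(data.table(
    chrom = "chr1", start = 1000L, end = 2000L, type = "DEL",
    length_bp = 1000L, sample_id = c("s1", "s2")))
  sc2 <- singleton_counts(two)
  expect_equal(sc2$n_singleton, c(0L, 0L))
  expect_equal(sc2$n_total, c(1L, 1L))
})

test_that("generator SV design is recovered exactly", {
  sh <- shared_sim()
  dsv <- merge_distinct(sh$ann$svs)
  truth <- sh$ann$truth$distinct_svs
  expect_equal(nrow(dsv), nrow(truth))
  ## per-type repeat overlap equals the planted design realization
  ro <- repeat_overlap(dsv, sh$ann$repeats)
  planted <- truth[, .(fraction = mean(repeat_overlap)), by = type]
  setkey(ro, type); setkey(planted, type)
  expect_equal(ro$fraction, planted$fraction)
  ## carrier spectrum: singleton totals match the truth
  sc <- singleton_counts(dsv)
  n_singl_truth <- truth[n_carriers == 1L, .N]
  expect_equal(sc[, sum(n_singleton)], n_singl_truth)
})

test_that("SV VCF round-trips through read_sv_vcf", {
  sh <- shared_sim()
  d <- withr::local_tempdir()
  write_sv_vcf(sh$ann$svs, d)
  s1 <- sort(unique(sh$ann$svs$sample_id))[1]
  got <- read_sv_vcf(file.path(d, paste0("sv_", s1, ".vcf")))
  want <- sh$ann$svs[sample_id == s1]
  setkey(got, chrom, start, type); setkey(want, chrom, start, type)
  expect_equal(got$start, want$start)
  expect_equal(got$type, want$type)
  expect_equal(got[type != "INS", end], want[type != "INS", end])
  expect_equal(got$length_bp, want$length_bp)
  expect_equal(unique(got$sample_id), s1)
})
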