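## Toy bubble topologies written directly as rGFA.
bubble_graph <- function(extra = character()) {
  f <- withr::local_tempfile(fileext = ".gfa", .local_envir = parent.frame())
  writeLines(c(
    "S\tr1\t*\tLN:i:100\tSN:Z:HdrR_1\tSO:i:0\tSR:i:0",
    "S\trm\t*\tLN:i:60\tSN:Z:HdrR_1\tSO:i:100\tSR:i:0",
    "S\tr2\t*\tLN:i:100\tSN:Z:HdrR_1\tSO:i:160\tSR:i:0",
    "S\tb1\t*\tLN:i:50\tSN:Z:MIKK_1\tSO:i:0\tSR:i:3",
    "L\tr1\t+\trm\t+\t0M", "L\trm\t+\tr2\t+\t0M",
    "L\tr1\t+\tb1\t+\t0M", "L\tb1\t+\tr2\t+\t0M",
    extra), f)
  parse_rgfa(f)
}

test_that("enumerate_alt_paths finds diamond and nested bubbles", {
  g <- bubble_graph()
  cand <- enumerate_alt_paths(g)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$members[[1]], "b1")
  expect_equal(cand$anchor_left, "r1")
  expect_equal(cand$anchor_right, "r2")
  expect_equal(cand[, c(span_start, span_end)], c(100, 160))

  ## second branch through two segments -> 2 distinct paths
  g2 <- bubble_graph(c(
    "S\tb2\t*\tLN:i:20\tSN:Z:MIKK_2\tSO:i:0\tSR:i:3",
    "S\tb3\t*\tLN:i:20\tSN:Z:MIKK_3\tSO:i:0\tSR:i:3",
    "L\tr1\t+\tb2\t+\t0M", "L\tb2\t+\tb3\t+\t0M", "L\tb3\t+\tr2\t+\t0M"))
  cand2 <- enumerate_alt_paths(g2)
  expect_equal(nrow(cand2), 2L)
  expect_setequal(vapply(cand2$members, paste, "", collapse = ","),
                  c("b1", "b2,b3"))
})

test_that("cycles among alt segments terminate and stay simple", {
  g <- bubble_graph(c(
    "S\tc1\t*\tLN:i:10\tSN:Z:MIKK_4\tSO:i:0\tSR:i:3",
    "S\tc2\t*\tLN:i:10\tSN:Z:MIKK_5\tSO:i:0\tSR:i:3",
    "L\tb1\t+\tc1\t+\t0M", "L\tc1\t+\tc2\t+\t0M", "L\tc2\t+\tb1\t+\t0M"))
  cand <- enumerate_alt_paths(g)
  ## every path is simple: no repeated member
  expect_true(all(vapply(cand$members, function(m)
    !anyDuplicated(m), logical(1))))
})

test_that("alt-path calling applies all five criteria on planted events", {
  sh <- shared_sim()
  cand <- enumerate_alt_paths(sh$sim$graph)
  annotation <- list(exons = sh$ann$exons, genes = sh$ann$genes)
  calls <- call_alt_paths(cand, sh$sim$divergences, sh$dna, sh$rna,
                          annotation)
  truth <- sh$sim$truth$alt_paths
  expect_equal(nrow(calls), sum(truth$qualifies))
  expect_equal(paste(calls$anchor_left, calls$anchor_right),
               paste(truth[qualifies == TRUE, anchor_left],
                     truth[qualifies == TRUE, anchor_right]))
  ## decoys fail exactly their planted criterion
  ev <- attr(calls, "evidence")
  dec <- merge(ev, truth[, .(anchor_left, anchor_right, kind)],
               by = c("anchor_left", "anchor_right"))
  expect_false(dec[kind == "length", pass_length])
  expect_true(dec[kind == "length",
                  pass_divergence & pass_dna & pass_rna & pass_exon])
  expect_false(dec[kind == "divergence", pass_divergence])
  expect_true(dec[kind == "divergence",
                  pass_length & pass_dna & pass_rna & pass_exon])
})

test_that("threshold relaxation is monotone for alt paths", {
  sh <- shared_sim()
  cand <- enumerate_alt_paths(sh$sim$graph)
  annotation <- list(exons = sh$ann$exons, genes = sh$ann$genes)
  base <- call_alt_paths(cand, sh$sim$divergences, sh$dna, sh$rna,
                         annotation)
  key <- function(x) paste(x$anchor_left, x$anchor_right)
  relax <- list(alt_path_params(min_len = 5000),
                alt_path_params(min_divergence = 0.2),
                alt_path_params(n_dna = 1),
                alt_path_params(n_rna = 1),
                alt_path_params(min_exons = 0))
  for (par in relax) {
    more <- call_alt_paths(cand, sh$sim$divergences, sh$dna, sh$rna,
                           annotation, par)
    expect_true(all(key(base) %in% key(more)))
  }
})

test_that("missing divergence values raise a named error", {
  sh <- shared_sim()
  cand <- enumerate_alt_paths(sh$sim$graph)
  annotation <- list(exons = sh$ann$exons, genes = sh$ann$genes)
  div <- sh$sim$divergences[-1]
  expect_error(call_alt_paths(cand, div, sh$dna, sh$rna, annotation),
               sh$sim$divergences$id[1], fixed = TRUE)
})

test_that("deletion calling uses gap, junction support and skipped exons", {
  sh <- shared_sim()
  annotation <- list(exons = sh$ann$exons, genes = sh$ann$genes)
  del <- call_deletions(sh$sim$graph, sh$dna, annotation)
  truth <- sh$sim$truth$deletions
  expect_equal(del$upstream_id, truth[qualifies == TRUE, upstream_id])
  expect_equal(del$span_bp, truth[qualifies == TRUE, gap_bp])
  expect_true(all(del$exons_skipped >= 1))
  expect_true(all(del$n_support >= ceiling(length(sh$dna) / 2)))
  ## support below q drops the call
  strict <- call_deletions(sh$sim$graph, sh$dna, annotation,
                           deletion_params(q = length(sh$dna) + 1L))
  expect_equal(nrow(strict), 0L)
})

test_that("relaxed scan is a superset containing sub-10kb events", {
  sh <- shared_sim()
  annotation <- list(exons = sh$ann$exons, genes = sh$ann$genes)
  del <- call_deletions(sh$sim$graph, sh$dna, annotation)
  rel <- relaxed_deletion_scan(sh$sim$graph, sh$dna, annotation)
  key <- function(x) paste(x$upstream_id, x$downstream_id)
  expect_true(all(key(del) %in% key(rel)))
  ## the 2 kb span decoy appears only in the relaxed scan
  span_decoy <- sh$sim$truth$deletions[kind == "span"]
  expect_false(key(span_decoy[, .(upstream_id, downstream_id)]) %in% key(del))
  expect_true(key(span_decoy[, .(upstream_id, downstream_id)]) %in% key(rel))
  ## empty profiles give an empty call set
  empty_rec <- sh$reads$dna[[1]][0]
  p0 <- list(structure(list(sample_id = "x", kind = "DNA",
                            bases = sh$dna[[1]]$bases * 0,
                            depth = sh$dna[[1]]$depth * 0,
                            junctions = numeric(0), ref_mean = 1),
                       class = "coverage_profile"))
  expect_equal(nrow(relaxed_deletion_scan(sh$sim$graph, p0, annotation)), 0L)
})

test_that("deletion gap arithmetic follows stable coordinates", {
  f <- withr::local_tempfile(fileext = ".gfa")
  writeLines(c(
    "S\tu\t*\tLN:i:500\tSN:Z:HdrR_1\tSO:i:1000\tSR:i:0",
    "S\tm\t*\tLN:i:18500\tSN:Z:HdrR_1\tSO:i:1500\tSR:i:0",
    "S\td\t*\tLN:i:500\tSN:Z:HdrR_1\tSO:i:20000\tSR:i:0",
    "L\tu\t+\tm\t+\t0M", "L\tm\t+\td\t+\t0M", "L\tu\t+\td\t+\t0M"), f)
  g <- parse_rgfa(f)
  p <- structure(list(sample_id = "s", kind = "DNA",
                      bases = setNames(numeric(3), c("u", "m", "d")),
                      depth = setNames(numeric(3), c("u", "m", "d")),
                      ## canonical orientation of the u+ -> d+ junction
                      junctions = setNames(10, "d->u-"), ref_mean = 10),
                 class = "coverage_profile")
  del <- call_deletions(g, list(p), annotation = NULL,
                        deletion_params(q = 1, min_exons = 0))
  expect_equal(del$span_bp, 18500)
  expect_equal(del[, c(del_start, del_end)], c(1500, 20000))
})
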