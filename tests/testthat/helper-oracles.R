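## Independent oracles and tiny fixture builders shared across tests.

library(data.table)

## ---- alignment oracle -------------------------------------------------
## Memoised recursion over alignment prefixes, lexicographically optimal in
## (edits, -matches); independent of the compiled DP in the package.
oracle_align <- function(a, b) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  memo <- new.env(parent = emptyenv())
  better <- function(x, y) {
    if (is.null(y)) return(x)
    if (x[1L] < y[1L] || (x[1L] == y[1L] && x[2L] > y[2L])) x else y
  }
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(av) && j > length(bv)) return(c(0L, 0L))
    best <- NULL
    if (i <= length(av) && j <= length(bv)) {
      r <- rec(i + 1L, j + 1L)
      eq <- av[i] == bv[j]
      best <- better(c(r[1L] + !eq, r[2L] + eq), best)
    }
    if (i <= length(av)) {
      r <- rec(i + 1L, j)
      best <- better(c(r[1L] + 1L, r[2L]), best)
    }
    if (j <= length(bv)) {
      r <- rec(i, j + 1L)
      best <- better(c(r[1L] + 1L, r[2L]), best)
    }
    memo[[key]] <- best
    best
  }
  res <- rec(1L, 1L)
  list(edits = res[1L], matches = res[2L],
       identity = res[2L] / sum(res))
}

## ---- coverage oracle --------------------------------------------------
## Normalised junction key: minimum of the two directional strings.
flip_o <- function(o) ifelse(o == "+", "-", "+")
norm_jkey <- function(f, fo, t, to) {
  pmin(paste0(f, fo, ">", t, to),
       paste0(t, flip_o(to), ">", f, flip_o(fo)))
}
## Re-normalise the package's junction names ("a+>b-") through norm_jkey.
renorm_jkeys <- function(keys) {
  if (length(keys) == 0L) return(character())
  parts <- strsplit(keys, ">", fixed = TRUE)
  f <- sub("[+-]$", "", vapply(parts, `[[`, "", 1L))
  fo <- sub(".*([+-])$", "\\1", vapply(parts, `[[`, "", 1L))
  t <- sub("[+-]$", "", vapply(parts, `[[`, "", 2L))
  to <- sub(".*([+-])$", "\\1", vapply(parts, `[[`, "", 2L))
  norm_jkey(f, fo, t, to)
}

## Brute-force per-base coverage and junction-traversal counter: builds a
## per-base owner vector for each record's path and counts covered bases /
## boundary crossings directly.
oracle_coverage <- function(records, seg_len) {
  bases <- setNames(numeric(length(seg_len)), names(seg_len))
  jcount <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(records))) {
    ids <- records$path_ids[[r]]
    ors <- records$path_orients[[r]]
    lens <- unname(seg_len[ids])
    owner <- rep(seq_along(ids), times = lens)
    ps <- records$pstart[r]
    pe <- records$pend[r]
    cov <- owner[(ps + 1L):pe]
    for (i in unique(cov))
      bases[ids[i]] <- bases[ids[i]] + sum(cov == i)
    if (length(ids) > 1L) {
      for (i in seq_len(length(ids) - 1L)) {
        ## traversed iff at least one covered base on each side of the
        ## boundary between members i and i+1
        if (any(cov <= i) && any(cov >= i + 1L)) {
          k <- norm_jkey(ids[i], ors[i], ids[i + 1L], ors[i + 1L])
          jcount[[k]] <- (jcount[[k]] %||% 0) + 1
        }
      }
    }
  }
  jl <- as.list(jcount)
  list(bases = bases,
       junctions = setNames(as.numeric(unlist(jl)), names(jl)))
}
`%||%` <- function(x, y) if (is.null(x)) y else x

## ---- random rGFA / GAF fixtures ---------------------------------------
## Writes a random test graph as rGFA text (own formatter, independent of
## write_rgfa): a REF_PRIMARY chain plus unanchored panel segments and
## random links.
write_random_rgfa <- function(path, n_seg) {
  n_ref <- max(2L, ceiling(n_seg / 2))
  n_alt <- n_seg - n_ref
  lens <- sample(20:150, n_seg, replace = TRUE)
  ids <- sprintf("q%03d", seq_len(n_seg))
  so <- cumsum(c(0L, lens[seq_len(n_ref - 1L)]))
  s_lines <- c(
    sprintf("S\t%s\t*\tLN:i:%d\tSN:Z:HdrR_1\tSO:i:%d\tSR:i:0",
            ids[seq_len(n_ref)], lens[seq_len(n_ref)], so),
    if (n_alt > 0L)
      sprintf("S\t%s\t*\tLN:i:%d\tSN:Z:MIKK_%d\tSO:i:0\tSR:i:3",
              ids[n_ref + seq_len(n_alt)], lens[n_ref + seq_len(n_alt)],
              seq_len(n_alt)))
  chain <- sprintf("L\t%s\t+\t%s\t+\t0M", ids[seq_len(n_ref - 1L)],
                   ids[2:n_ref])
  n_extra <- sample(0:10, 1L)
  extra <- if (n_extra > 0L) {
    a <- sample(ids, n_extra, replace = TRUE)
    b <- sample(ids, n_extra, replace = TRUE)
    sprintf("L\t%s\t%s\t%s\t%s\t0M", a,
            sample(c("+", "-"), n_extra, TRUE), b,
            sample(c("+", "-"), n_extra, TRUE))
  } else character()
  writeLines(c(s_lines, chain, extra), path)
  invisible(list(ids = ids, lens = setNames(lens, ids)))
}

## Random GAF over a graph's segments (own formatter).
write_random_gaf <- function(path, seg_len, n_rec) {
  lines <- character(n_rec)
  for (r in seq_len(n_rec)) {
    k <- sample(1:4, 1L)
    ids <- sample(names(seg_len), k)
    ors <- sample(c(">", "<"), k, replace = TRUE)
    plen <- sum(seg_len[ids])
    ps <- sample.int(plen, 1L) - 1L
    pe <- ps + sample.int(plen - ps, 1L)
    lines[r] <- paste(sprintf("read%04d", r), pe - ps, 0, pe - ps, "+",
                      paste0(ors, ids, collapse = ""), plen, ps, pe,
                      pe - ps, pe - ps, sample(0:60, 1L), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- misc -------------------------------------------------------------
## BH step-up closed form, written directly from the definition:
## q_(i) = min over j with p_(j) >= p_(i) of m * p_(j) / rank(j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranks <- seq_len(m)
  q_sorted <- vapply(ranks, function(i)
    min(1, min(m * p[o][i:m] / ranks[i:m])), numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

## Compositions of n into k ordered positive parts (for KW group sweeps).
compositions <- function(n, k) {
  if (k == 1L) return(list(n))
  out <- list()
  for (first in seq_len(n - k + 1L)) {
    for (rest in compositions(n - first, k - 1L))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

## A small deterministic simulated panel shared by several test files.
tiny_cfg <- function(seed = 42L, ...) {
  defaults <- list(seed = seed, alt_qualifying = 1L, del_qualifying = 1L,
                   alt_decoys = c("length", "divergence"),
                   del_decoys = "span", n_rna_samples = 10L,
                   alt_rna_carriers = 8L, n_bg_genes = 3L,
                   meth_n_islands = 40L, meth_n_dmr = 8L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

## Simulate the tiny panel once per test run (graph, reads, profiles,
## annotation) and memoise it for every test file.
.shared_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.shared_env$sim)) {
    cfg <- tiny_cfg()
    sim <- simulate_graph(cfg)
    reads <- simulate_gaf(cfg, sim)
    dna <- lapply(names(reads$dna), function(s)
      compute_profile(reads$dna[[s]], sim$graph, s, "DNA"))
    names(dna) <- names(reads$dna)
    rna <- lapply(names(reads$rna), function(s)
      compute_profile(reads$rna[[s]], sim$graph, s, "RNA"))
    names(rna) <- names(reads$rna)
    ann <- simulate_annotation(cfg, sim)
    .shared_env$cfg <- cfg
    .shared_env$sim <- sim
    .shared_env$reads <- reads
    .shared_env$dna <- dna
    .shared_env$rna <- rna
    .shared_env$ann <- ann
  }
  .shared_env
}
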