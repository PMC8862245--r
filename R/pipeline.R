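## End-to-end orchestration: simulate (or load) inputs, compute coverage,
## call graph SVs, classify core genes, annotate SV sets, test methylation,
## and write machine-readable summaries with full provenance.

#' Write simulated inputs to a directory
#'
#' Emits every input the pipeline consumes: `graph.gfa`, per-sample GAF
#' under `gaf/`, `genes.gff3`, `islands.bed`, `repeats.bed`, `pli.tsv`,
#' per-sample SV VCFs under `sv/`, per-sample methylation calls under
#' `meth/`, and `truth.json`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @return invisibly, the in-memory simulation objects (`sim`, `reads`,
#'   `ann`, `meth`).
#' @export
simulate_all <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_graph(cfg)
  reads <- simulate_gaf(cfg, sim)
  ann <- simulate_annotation(cfg, sim)
  meth <- simulate_meth(cfg, ann$islands)

  write_rgfa(sim$graph, file.path(dir, "graph.gfa"))
  gaf_dir <- file.path(dir, "gaf")
  dir.create(gaf_dir, showWarnings = FALSE)
  for (s in names(reads$dna))
    write_gaf(reads$dna[[s]], file.path(gaf_dir, paste0("dna_", s, ".gaf")))
  for (s in names(reads$rna))
    write_gaf(reads$rna[[s]], file.path(gaf_dir, paste0("rna_", s, ".gaf")))
  fwrite(sim$divergences, file.path(dir, "divergences.tsv"), sep = "\t")
  write_gff3(ann$genes, ann$exons, file.path(dir, "genes.gff3"))
  write_bed(ann$islands, file.path(dir, "islands.bed"))
  write_bed(ann$repeats, file.path(dir, "repeats.bed"))
  fwrite(ann$pli, file.path(dir, "pli.tsv"), sep = "\t")
  write_sv_vcf(ann$svs, file.path(dir, "sv"))
  meth_dir <- file.path(dir, "meth")
  dir.create(meth_dir, showWarnings = FALSE)
  for (s in unique(meth$calls$sample_id))
    fwrite(meth$calls[sample_id == s],
           file.path(meth_dir, paste0("meth_", s, ".tsv")), sep = "\t")

  truth <- list(
    alt_paths = sim$truth$alt_paths,
    deletions = sim$truth$deletions,
    distinct_svs = ann$truth$distinct_svs,
    repeat_fraction = ann$truth$repeat_fraction,
    dmr_islands = meth$truth$islands
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, reads = reads, ann = ann, meth = meth))
}

#' Pipeline run configuration
#'
#' Every threshold is serialised into the run's provenance record.
#'
#' @param sim a [sim_config()] used when no `input_dir` is given.
#' @param input_dir directory of pre-generated inputs (layout of
#'   [simulate_all()]); `NULL` simulates in memory.
#' @param theta segment-usage threshold.
#' @param alt_params,del_params calling thresholds
#'   ([alt_path_params()], [deletion_params()]).
#' @param merge_reciprocal,merge_max_shift SV merging parameters.
#' @param pli_eps pLI clamp.
#' @param min_reads,min_sites,min_samples methylation coverage filters.
#' @param alpha methylation FDR level.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       theta = 0.05,
                       alt_params = alt_path_params(),
                       del_params = deletion_params(),
                       merge_reciprocal = 0.8, merge_max_shift = 1000,
                       pli_eps = 1e-16,
                       min_reads = 5L, min_sites = 3L, min_samples = 4L,
                       alpha = 0.01) {
  structure(as.list(environment()), class = "run_config")
}

run_stage <- function(status, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = eval.parent(substitute(expr))),
                  error = function(e)
                    list(ok = FALSE, value = NULL, error = conditionMessage(e)))
  status[[name]] <- if (res$ok) list(status = "ok")
                    else list(status = "error", message = res$error)
  list(status = status, value = res$value, ok = res$ok)
}

#' Run the full pipeline
#'
#' Stages: inputs (simulate or load), coverage, graph SV calling, core
#' genes, SV annotation, methylation.  A failing stage is isolated: its
#' error is recorded in the summary and later stages that do not depend on
#' it still run.  Deterministic given the configuration seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory for result tables, `summary.json` and
#'   `provenance.json`.
#' @return invisibly, a list of stage results and the summary list.
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  results <- list()

  ## ---- inputs ----
  st <- run_stage(status, "inputs", {
    if (is.null(config$input_dir)) {
      sim <- simulate_graph(config$sim)
      reads <- simulate_gaf(config$sim, sim)
      ann_raw <- simulate_annotation(config$sim, sim)
      meth_raw <- simulate_meth(config$sim, ann_raw$islands)
      annotation <- structure(
        list(genes = copy(ann_raw$genes)[, `:=`(gene_start = start,
                                                gene_end = end)],
             exons = ann_raw$exons), class = "gene_annotation")
      list(graph = sim$graph, dna_gaf = reads$dna, rna_gaf = reads$rna,
           divergences = sim$divergences,
           annotation = annotation, islands = ann_raw$islands,
           repeats = ann_raw$repeats, pli = ann_raw$pli, svs = ann_raw$svs,
           meth_calls = meth_raw$calls)
    } else {
      d <- config$input_dir
      graph <- parse_rgfa(file.path(d, "graph.gfa"))
      gaf_files <- list.files(file.path(d, "gaf"), full.names = TRUE)
      dna_files <- grep("/dna_", gaf_files, value = TRUE)
      rna_files <- grep("/rna_", gaf_files, value = TRUE)
      name_of <- function(f) sub("^(dna|rna)_(.*)\\.gaf$", "\\2", basename(f))
      dna_gaf <- setNames(lapply(dna_files, parse_gaf),
                          vapply(dna_files, name_of, character(1)))
      rna_gaf <- setNames(lapply(rna_files, parse_gaf),
                          vapply(rna_files, name_of, character(1)))
      gff <- file.path(d, "genes.gff3")
      if (!file.exists(gff)) stop("annotation file missing: ", gff)
      annotation <- load_annotation(gff)
      islands <- read_bed(file.path(d, "islands.bed"))
      repeats <- read_bed(file.path(d, "repeats.bed"))
      pli <- read_pli(file.path(d, "pli.tsv"))
      div_file <- file.path(d, "divergences.tsv")
      divergences <- if (file.exists(div_file)) fread(div_file) else NULL
      sv_files <- list.files(file.path(d, "sv"), pattern = "\\.vcf$",
                             full.names = TRUE)
      svs <- rbindlist(lapply(sv_files, read_sv_vcf), fill = TRUE)
      meth_files <- list.files(file.path(d, "meth"), full.names = TRUE)
      meth_calls <- read_meth_calls(meth_files)
      list(graph = graph, dna_gaf = dna_gaf, rna_gaf = rna_gaf,
           divergences = divergences,
           annotation = annotation, islands = islands, repeats = repeats,
           pli = pli, svs = svs, meth_calls = meth_calls)
    }
  })
  status <- st$status
  inputs <- st$value
  if (!st$ok) {
    smry <- list(stages = status)
    jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(status = status, summary = smry)))
  }
  g <- inputs$graph

  ## ---- coverage ----
  st <- run_stage(status, "coverage", {
    dna <- lapply(names(inputs$dna_gaf), function(s)
      compute_profile(inputs$dna_gaf[[s]], g, s, "DNA"))
    names(dna) <- names(inputs$dna_gaf)
    rna <- lapply(names(inputs$rna_gaf), function(s)
      compute_profile(inputs$rna_gaf[[s]], g, s, "RNA"))
    names(rna) <- names(inputs$rna_gaf)
    um <- usage_matrix(dna, config$theta)
    frac <- rbindlist(lapply(dna, function(p)
      origin_fractions(p, g)[, sample_id := p$sample_id]))
    xu <- cross_usage(dna, g, config$theta)
    fwrite(frac, file.path(out_dir, "origin_fractions.tsv"), sep = "\t")
    fwrite(xu, file.path(out_dir, "cross_usage.tsv"), sep = "\t")
    list(dna = dna, rna = rna, usage = um)
  })
  status <- st$status
  cov <- st$value

  ## ---- graph SV ----
  st <- run_stage(status, "graph_sv", {
    if (is.null(cov)) stop("coverage stage failed")
    cand <- enumerate_alt_paths(g)
    ## an external divergence table (aligner output or simulator truth)
    ## takes precedence; the internal unit-cost identity saturates near
    ## 0.46 divergence so it cannot support the > 0.5 criterion
    div <- if (!is.null(inputs$divergences)) inputs$divergences
           else path_divergences(g, cand)
    alt <- call_alt_paths(cand, div, cov$dna, cov$rna, inputs$annotation,
                          config$alt_params)
    del <- call_deletions(g, cov$dna, inputs$annotation, config$del_params)
    rel <- relaxed_deletion_scan(g, cov$dna, inputs$annotation,
                                 config$del_params)
    fwrite(alt[, .(anchor_left, anchor_right, stable_name, span_start,
                   span_end, cum_length, max_divergence, dna_support,
                   rna_support, exon_overlap)],
           file.path(out_dir, "alt_paths.tsv"), sep = "\t")
    fwrite(del, file.path(out_dir, "deletions.tsv"), sep = "\t")
    fwrite(rel, file.path(out_dir, "deletions_relaxed.tsv"), sep = "\t")
    list(alt = alt, del = del, relaxed = rel)
  })
  status <- st$status
  gsv <- st$value

  ## ---- core genes ----
  st <- run_stage(status, "core_genes", {
    if (is.null(cov)) stop("coverage stage failed")
    core <- core_segments(cov$usage, g)
    cls <- classify_genes(inputs$annotation, core, g)
    fwrite(cls, file.path(out_dir, "gene_classes.tsv"), sep = "\t")
    cls
  })
  status <- st$status
  gene_cls <- st$value

  ## ---- SV annotation ----
  st <- run_stage(status, "sv_annotation", {
    distinct <- merge_distinct(inputs$svs, config$merge_reciprocal,
                               config$merge_max_shift)
    genes_iv <- inputs$annotation$genes[, .(gene_id, chrom,
                                            start = gene_start,
                                            end = gene_end)]
    scored <- pli_lod(distinct, genes_iv, inputs$pli, config$pli_eps)
    rpt <- repeat_overlap(distinct, inputs$repeats)
    singl <- singleton_counts(distinct)
    fwrite(scored[, .(chrom, start, end, type, length_bp, n_carriers, lod)],
           file.path(out_dir, "sv_annotated.tsv"), sep = "\t")
    fwrite(rpt, file.path(out_dir, "sv_repeat_overlap.tsv"), sep = "\t")
    fwrite(singl, file.path(out_dir, "sv_singletons.tsv"), sep = "\t")
    list(distinct = scored, repeat_overlap = rpt, singletons = singl)
  })
  status <- st$status
  svann <- st$value

  ## ---- methylation ----
  st <- run_stage(status, "methylation", {
    sites <- aggregate_sites(inputs$meth_calls, config$min_reads)
    meth <- test_islands(sites, inputs$islands, config$min_sites,
                         config$min_samples, config$alpha)
    rep_ <- dmr_report(meth)
    tssd <- tss_distance_summary(
      meth$tests, inputs$annotation$genes[, .(chrom, tss)])
    fwrite(meth$tests, file.path(out_dir, "meth_islands.tsv"), sep = "\t")
    if (nrow(rep_$significant) > 0L)
      fwrite(data.table(island = rownames(rep_$matrix), rep_$matrix),
             file.path(out_dir, "meth_cluster_matrix.tsv"), sep = "\t")
    list(tests = meth, report = rep_, tss = tssd)
  })
  status <- st$status
  meth_res <- st$value

  counts <- list(
    n_segments = nrow(g$segments),
    n_links = nrow(g$links),
    n_dna_samples = length(inputs$dna_gaf),
    n_rna_samples = length(inputs$rna_gaf),
    n_alt_paths = if (!is.null(gsv)) nrow(gsv$alt) else NA,
    n_deletions = if (!is.null(gsv)) nrow(gsv$del) else NA,
    n_deletions_relaxed = if (!is.null(gsv)) nrow(gsv$relaxed) else NA,
    gene_classes = if (!is.null(gene_cls))
      as.list(table(gene_cls$class_call)) else NA,
    n_distinct_svs = if (!is.null(svann)) nrow(svann$distinct) else NA,
    n_islands_tested = if (!is.null(meth_res))
      nrow(meth_res$tests$tests) else NA,
    n_dmr = if (!is.null(meth_res))
      sum(meth_res$tests$tests$significant) else NA
  )
  smry <- list(stages = status, counts = counts)
  jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(seed = config$sim$seed, theta = config$theta,
               alt_params = config$alt_params,
               del_params = config$del_params,
               merge_reciprocal = config$merge_reciprocal,
               merge_max_shift = config$merge_max_shift,
               pli_eps = config$pli_eps, min_reads = config$min_reads,
               min_sites = config$min_sites,
               min_samples = config$min_samples, alpha = config$alpha)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(status = status, summary = smry, coverage = cov,
                 graph_sv = gsv, gene_classes = gene_cls,
                 sv_annotation = svann, methylation = meth_res))
}
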