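## Simulation configuration: one stated world for the synthetic panel.
##
## Defaults mirror the study design where it states one: 12 panel samples
## including 3 sibling pairs, ~20x long-read depth with read lengths around
## the reported median N50 (~7 kb), 50 RNA samples, a 16% reference repeat
## fraction, methylation LLR mixture at +/-2.5, and FDR 1%.  Event shape
## parameters (spans, divergences, carrier counts) follow the calling
## thresholds' worked examples: qualifying events clear every criterion
## with margin, decoys violate exactly one criterion each.

#' Simulation configuration
#'
#' @param seed master seed; fully determines every simulated byte.
#' @param n_samples number of DNA panel samples (default 12).
#' @param sib_pairs number of sibling pairs among the first samples.
#' @param depth mean long-read depth per sample (Poisson lambda).
#' @param read_len DNA read length (bp).
#' @param n_rna_samples,rna_read_len RNA sample count and read length.
#' @param rna_exon_depth RNA read depth over annotated exons.
#' @param bg_seg_len,anchor_len background / anchor reference segment
#'   lengths (bp).
#' @param alt_qualifying number of qualifying alternative-path events.
#' @param alt_decoys character vector of alt-path decoys, each the single
#'   criterion it violates: `length`, `divergence`, `dna_support`,
#'   `rna_support`, `exon`.
#' @param alt_ref_span reference-allele span of an alt bubble (bp); decoy
#'   `length` uses `alt_decoy_span`.
#' @param alt_decoy_span reference span of the `length` decoy.
#' @param alt_members member segments per alt branch.
#' @param alt_hi_div,alt_lo_div target divergence of the divergent member /
#'   the remaining members.
#' @param alt_decoy_div divergence of every member of the `divergence`
#'   decoy (below 0.5).
#' @param alt_dna_carriers,alt_rna_carriers supporting samples of a
#'   qualifying event; decoys use `alt_decoy_dna` / `alt_decoy_rna`.
#' @param alt_decoy_dna,alt_decoy_rna carrier counts of support decoys.
#' @param del_qualifying number of qualifying deletion events.
#' @param del_decoys character vector of deletion decoys: `span`,
#'   `junction_support`, `exon_skip`.
#' @param del_gap deleted span of a qualifying event (bp);
#'   `del_decoy_gap` for the `span` decoy (> 1 kb, < 10 kb).
#' @param del_decoy_gap deleted span of the `span` decoy.
#' @param del_carriers,del_decoy_carriers supporting samples.
#' @param n_ref_alt_bubbles short low-divergence bubbles from the
#'   alternative reference assemblies (graph-statistics realism; never
#'   called).
#' @param n_bg_genes background genes outside events.
#' @param theta segment-usage threshold used by the pipeline default.
#' @param repeat_fraction fraction of reference bases classified as repeat.
#' @param sv_n_per_type distinct SVs simulated per type.
#' @param sv_samples number of SV-called samples (default 9).
#' @param sv_repeat_design named numeric, per-type target fraction of SVs
#'   overlapping repeats.
#' @param meth_n_islands,meth_n_dmr CpG islands and planted DMRs.
#' @param meth_sites_per_island,meth_reads_per_site island geometry.
#' @param meth_mu,meth_sigma LLR mixture component mean (+/-) and sd.
#' @param meth_base_rates methylation rates non-DMR islands draw from.
#' @param meth_dmr_delta methylation-rate offset between the low and high
#'   methylation states at DMR islands.
#' @param meth_dmr_design `"lineage"` (default: each lineage — a sibling
#'   pair or a single line — draws its own low/high state at a DMR island,
#'   i.e. line-level heritable methylation) or `"group"` (a fixed
#'   half-vs-half panel split, the two-group power setting).
#' @param meth_lineage_sd sd of the per-lineage (shared by siblings)
#'   methylation-rate jitter; 0 makes non-DMR islands exchangeable across
#'   samples (the null world for type-I-error checks).
#' @param meth_sib_noise sd of the rate jitter between sibling profiles.
#' @param alpha FDR level (default 0.01).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 12L, sib_pairs = 3L,
                       depth = 20, read_len = 7000L,
                       n_rna_samples = 50L, rna_read_len = 400L,
                       rna_exon_depth = 5,
                       bg_seg_len = 2000L, anchor_len = 2000L,
                       alt_qualifying = 3L,
                       alt_decoys = c("length", "divergence", "dna_support",
                                      "rna_support", "exon"),
                       alt_ref_span = 10000L, alt_decoy_span = 6000L,
                       alt_members = 3L,
                       alt_hi_div = 0.65, alt_lo_div = 0.10,
                       alt_decoy_div = 0.30,
                       alt_dna_carriers = 3L, alt_rna_carriers = 10L,
                       alt_decoy_dna = 1L, alt_decoy_rna = 3L,
                       del_qualifying = 3L,
                       del_decoys = c("span", "junction_support",
                                      "exon_skip"),
                       del_gap = 15000L, del_decoy_gap = 2000L,
                       del_carriers = 10L, del_decoy_carriers = 3L,
                       n_ref_alt_bubbles = 2L,
                       n_bg_genes = 10L,
                       theta = 0.05,
                       repeat_fraction = 0.16,
                       sv_n_per_type = 60L, sv_samples = 9L,
                       sv_repeat_design = c(DEL = 0.72, DUP = 0.63,
                                            INV = 0.81, TRA = 0.35,
                                            INS = 0.21),
                       meth_n_islands = 300L, meth_n_dmr = 40L,
                       meth_sites_per_island = 10L,
                       meth_reads_per_site = 20L,
                       meth_mu = 2.5, meth_sigma = 1,
                       meth_base_rates = c(0.1, 0.5, 0.9),
                       meth_dmr_delta = 0.8,
                       meth_dmr_design = c("lineage", "group"),
                       meth_lineage_sd = 0.05,
                       meth_sib_noise = 0.02,
                       alpha = 0.01) {
  stopifnot(n_samples >= 2L, sib_pairs * 2L <= n_samples,
            alt_hi_div > 0.5, alt_decoy_div < 0.5,
            del_gap > 10000L, del_decoy_gap > 1000L, del_decoy_gap < 10000L)
  meth_dmr_design <- match.arg(meth_dmr_design)
  cfg <- as.list(environment())
  cfg$samples <- sprintf("L%02d", seq_len(n_samples))
  cfg$rna_samples <- sprintf("R%02d", seq_len(n_rna_samples))
  cfg$contig <- "HdrR_1"
  structure(cfg, class = "sim_config")
}
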