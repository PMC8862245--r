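---
title: "Methods: graph coverage, structural variation and methylation in panelgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph coverage, structural variation and methylation in panelgraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`panelgraph` analyses a reference pangenome variation graph built
iteratively from a primary reference genome, one or more alternative
reference assemblies, and a panel of inbred-line draft assemblies.  In
rGFA, every segment carries its origin contig (`SN`), the 0-based offset on
that contig (`SO`), and the assembly rank (`SR`, 0 for the primary
reference).  Prefixing each contig with its assembly name makes segment
provenance unambiguous, and segments anchored on the primary reference
retain *stable coordinates*, so graph results can be projected back onto
the familiar linear genome.  The package covers five analysis layers:

1. **Graph model** — parsing, validation, per-origin summary statistics
   (counts, total/median length, longest segment, N50), BED export of
   reference segments on stable coordinates.
2. **Coverage** — per-sample, length-normalised segment depths and
   junction traversal counts from GAF alignments; usage calls against a
   fraction of the sample's reference mean depth; origin fractions of
   aligned bases; cross-usage of non-reference segments across samples.
3. **Graph structural variation** — divergent alternative paths (bubbles)
   and large-scale deletions called from topology, divergence, coverage
   support and exon overlap.
4. **Core genes** — classification of annotated genes as core /
   fragmented / absent from the share of coding-exon bases inside
   segments used by every panel sample.
5. **Methylation** — per-read CpG log-likelihood ratios aggregated to
   site medians, island-level Kruskal-Wallis tests across samples,
   Benjamini-Hochberg FDR control, per-sample methylation states and a
   clustering matrix, and TSS-distance summaries.

A sixth module simulates every input with recorded ground truth, and a
pipeline layer orchestrates end-to-end runs with provenance.

# Coverage definitions

For a GAF record with path interval `[pstart, pend)` over an ordered list
of segments, aligned bases are attributed to each member by interval
intersection with the member's span on the concatenated path.  Depth of a
segment is aligned bases divided by segment length.  The reference mean
depth `ref_mean` is **length-weighted**: total aligned bases on
REF_PRIMARY segments divided by their total length.  This is robust to
fragmented reference segmentation; an unweighted per-segment mean is
available via `ref_mean_mode = "simple"`.

A junction (canonical, orientation-free link) is counted as traversed when
the alignment covers **at least one base on each side** of the boundary
between two consecutive path members.  A literal half-open reading
("boundary position inside `[pstart, pend)`") is not symmetric under
reversing the record's path, and junction counts are required to be
orientation-invariant, so the symmetric rule is used.

Junction traversal counts are compared against `ref_mean`, a depth — a
deliberate cross-unit comparison: a read that traverses a junction
contributes exactly one count, so for uniformly covering reads the count
at a point approximates the depth there.

RNA profiles are normalised by their own RNA `ref_mean`, independent of
the DNA normalisation.

# Structural-variant calling

**Alternative paths.**  Candidates are simple paths that leave and rejoin
REF_PRIMARY segments while traversing only non-reference segments,
enumerated by bounded depth-first search (defaults: 50 members,
10 000 candidates; truncation is flagged, never silent).  Out-and-back
paths that return to their starting anchor are topological artifacts of
orientation-free traversal and are excluded.  A candidate is called when
all five criteria hold (all configurable, defaults in parentheses):

* cumulative member length strictly greater than `min_len` (10 000 bp);
* at least one member segment with divergence strictly above 0.5
  ("containing" a divergent segment — an *any-member* rule; an
  *all-members* mode is a flag);
* at least `n_dna` (2) DNA samples whose **every** member segment reaches
  50% of that sample's `ref_mean` (a sample must support the whole
  haplotype; an any-member mode is a flag);
* at least `n_rna` (8) RNA samples with **any** member at 10% of the RNA
  `ref_mean` (transcription may cover only part of an insertion);
* at least one annotated exon overlapping the reference span between the
  anchors.

**Divergence input.**  Identity here is matches / alignment columns of a
unit-cost global alignment, made deterministic by taking, among
minimum-edit alignments, the one with the most matches (compiled DP).
This metric **saturates**: two unrelated DNA sequences of comparable
length align at roughly 0.54 identity, because with a 4-letter alphabet a
chance match is never far away.  Divergence above 0.5 is therefore not
reachable by this internal metric, which is why the caller takes a
divergence table as input — in practice the output of a genomic aligner
(the original analysis used one), in testing the simulator's recorded
per-member divergence.  `path_divergences()` remains available as an
internal fallback for low-divergence work, with this caveat documented.

**Deletions.**  Candidate junctions join two REF_PRIMARY segments on the
same stable contig with consistent orientation (inversion-like links are
excluded and counted).  A junction is called a deletion when the
stable-coordinate gap strictly exceeds `min_gap` (10 000 bp), the
traversal count reaches 50% of `ref_mean` in at least `q` samples
(default: half the panel, rounded up; a published figure caption uses 9 of
12, reachable via `q = 9`), and at least one annotated exon is **fully
contained** in the deleted interval.  The relaxed scan lowers the gap to
1 000 bp and disables the exon criterion, yielding a superset of the
strict calls.

# Core genes

The core segment set is the intersection of usage across samples at a
usage threshold (default 5% of `ref_mean`).  A design note: adding *all*
REF_PRIMARY segments "by definition of reference presence" would make
every reference-anchored gene trivially 100% covered and the
classification vacuous; the package therefore requires read support in
every sample for reference segments too (the union variant is available
as `include_ref = TRUE`).  A gene's covered fraction is the base-level
intersection of its merged coding-exon intervals with core reference
segments' stable intervals; `core` strictly above 0.95, `absent` at
exactly 0, `fragmented` otherwise.  CDS intervals are used by default
(all-exon mode is a flag), and a fully-contained-exon counting mode is
available.

# SV annotation

Per-sample reference-anchored call sets (VCF with `SVTYPE`/`SVLEN`/`END`,
or TSV) are merged into distinct SVs by same-type reciprocal overlap
(default 0.8) with breakpoint shifts at most 1 000 bp, closed
transitively so the merge is order-independent.  Each distinct SV gets:

* a **pLI LOD**: the sum over overlapping genes of `log10(p'/(1-p'))`
  with `p' = clamp(pli, eps, 1-eps)`, `eps = 1e-16` by default.  The
  clamp keeps scores finite for pLI of exactly 0 or 1; published LOD
  values near 57 for a pLI printed as "1" imply a high-precision
  near-one value upstream, so the clamp is exposed.  SVs overlapping no
  scored gene report `NA`, distinct from 0.
* **repeat overlap**: per-type fraction of distinct SVs touching at least
  one repeat base (repeats merged, strands ignored); translocation
  "regions" are both breakends padded by 100 bp, a convention chosen here
  because the upstream treatment is unstated.
* **singleton counts**: per sample and type, distinct SVs carried by
  exactly one sample.

# Methylation

Per-read log-likelihood ratios (natural log, methylated over
unmethylated) are aggregated to per-position medians per sample;
positions with fewer than `min_reads` (5) reads are dropped.  For each
CpG island, all site medians of samples contributing at least `min_sites`
(3) positions are compared across samples with the Kruskal-Wallis test
(chi-squared approximation with tie correction; the all-tied degenerate
case is defined as H = 0, p = 1).  Islands with fewer than `min_samples`
(4) contributing samples are skipped with a reason code.  The
"sufficient coverage" filters are undefined upstream; the defaults here
are recorded in every run's provenance.  P-values are adjusted by the
Benjamini-Hochberg step-up rule; the significance level defaults to FDR
1%.  A sample's island state is `methylated` at island-median LLR >= 1,
`unmethylated` at <= -1, and `ambiguous` in between — the heatmap
ambiguity band.  Island medians are medians of site medians (consistent
with the test's observations); pooling raw read LLRs instead is the
documented alternative.  CpG positions are taken as the forward-strand C
of the dyad; islands are an input BED (no island detection is
implemented).

# The synthetic world

The generator's defaults state one world and are not tuned per test:

* 12 DNA samples with 3 sibling pairs, read length 7 000 bp (the reported
  read-length scale), Poisson depth lambda = 20; 50 RNA samples.
* Alternative-path events: a 10 kb reference allele replaced by a branch
  whose members are mutated copies of reference slices; one short member
  at divergence 0.65, the rest at 0.10; 3 DNA and 10 RNA carriers;
  decoys violate exactly one criterion each (8 kb cumulative length /
  all-member divergence 0.30 / 1 DNA carrier / 3 RNA carriers / no exon).
* Deletions: 15 kb gaps with 10 carriers and a skipped exon; decoys use a
  2 kb gap, 3 carriers, or no exon.
* Repeats tile 16% of reference bases (the reported genome-wide repeat
  fraction); SV carrier counts follow 1 + Binomial(8, 0.15), dominated by
  singletons; per-type repeat-overlap fractions follow the reported
  percentages (72/63/81/35/21 for DEL/DUP/INV/TRA/INS).
* Methylation: 10 sites per island, 20 reads per site, LLR mixture at
  +/-2.5 with sd 1.  At a planted DMR island every *lineage* (a sibling
  pair, or a single line) draws its own low/high methylation state (rate
  difference 0.8, forced to be mixed across lineages) — line-level,
  heritable methylation whose profile is duplicated within sibling pairs,
  which is what makes siblings cluster together.  A fixed half-vs-half
  split (`meth_dmr_design = "group"`) serves two-group power studies.
  Sibling pairs additionally share a per-lineage rate jitter (sd 0.05)
  plus small individual noise (sd 0.02); setting both to zero yields the
  exchangeable null world used for type-I-error checks.

Mutation to a target divergence uses a substitution+insertion operator (a
mutated base becomes three random bases) whose intensity is calibrated by
bisection against the package's own identity — necessary because pure
substitution cannot push unit-cost identity below the ~0.54 random floor.
Calibration runs on a capped 1.5 kb prefix (same random draws) and is
verified on the full sequence, with realized divergence recorded in the
truth (within 0.02 of target).

What a green test does **not** establish: the generator draws read paths
directly (no sequence-level read simulation, no aligner, no mapping
error, no secondary alignments), repeats are uniform tiles rather than
repeat families, RNA coverage is uniform over exons rather than
expression-shaped, and methylation sites are evenly spaced.  Detection
margins on real data are accordingly expected to be narrower than the
clean separations seen here.

# Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3 and VCF conversions
  happen at the parser boundary.  BED stays in its native convention.
* Links are canonicalised so either traversal direction maps to one
  junction key (the lexicographically smaller oriented head first).
* Pipeline configuration is JSON (the plain-text config of choice given
  the installed stack); every threshold is serialised into
  `provenance.json`, and reruns with one seed are byte-identical.
* The usage threshold appears in the source material as both 5% and 10%
  in different displays; both are exposed (`theta`), with 0.05 as the
  pipeline default and no privileged value.
* Kruskal-Wallis is implemented in-package (10 lines) rather than through
  `stats::kruskal.test` because the all-tied case must be defined (the
  base oracle returns NaN); the base implementation remains the test
  oracle elsewhere.
* Sub-seeds for the simulator stages are derived arithmetically from the
  master seed and stay below 2^31.

# Known limitations

* The internal identity metric is global and unit-cost; it is not a
  substitute for a genomic aligner on highly divergent sequence (see the
  saturation note above).
* Bubble enumeration is exhaustive only up to its stated bounds; graphs
  with extremely dense variation may hit the candidate cap (flagged).
* Deletion calling ignores inversion-like junctions (counted, not
  interpreted), and nested events are reported independently, not as a
  hierarchy.
* `merge_distinct` is a minimal reciprocal-overlap merger for carrier
  counting, not a re-implementation of a full SV-merging toolchain.
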