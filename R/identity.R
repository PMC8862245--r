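## Sequence identity under unit-cost global alignment.
##
## Identity is defined as matches / alignment columns of a unit-cost global
## alignment (Levenshtein alignment).  Co-optimal alignments can disagree on
## their match count, so the implementation takes the maximum match count M
## among minimum-edit alignments (compiled DP in src/); columns are then
## M + edits (every edit occupies one column) and the resulting identity is
## symmetric and deterministic.

#' Identity of two sequences under unit-cost global alignment
#'
#' @param a,b non-empty nucleotide strings.
#' @return list with `identity` (matches / alignment columns, in \[0,1\]),
#'   `aligned_length` (alignment columns), `matches` (maximum matches over
#'   minimum-edit alignments), `edits` (Levenshtein distance).  Identity is
#'   symmetric in `a` and `b` and equals `1 - edits / aligned_length`.
#' @export
alignment_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L,
            length(b) == 1L, !is.na(a), !is.na(b), nzchar(a), nzchar(b))
  st <- edit_alignment_stats(a, b)
  edits <- st[1L]
  matches <- st[2L]
  cols <- matches + edits
  list(identity = matches / cols, aligned_length = cols,
       matches = matches, edits = edits)
}

#' Divergence record for a graph segment against a reference window
#'
#' Aligns a segment's sequence globally against a reference window and
#' reports identity (divergence is `1 - identity`).  Precomputed divergence
#' tables may be supplied to downstream callers instead when sequences are
#' absent or externally aligned values are preferred.
#'
#' @param g a `pan_graph`.
#' @param id segment id.
#' @param ref_window reference nucleotide string to align against.
#' @return one-row data.table: `id`, `identity_frac`, `divergence`,
#'   `aligned_length`.
#' @export
segment_identity <- function(g, id, ref_window) {
  lookup <- id
  seg <- g$segments[J(lookup)]
  ## keyed joins echo the join value in the key column; a miss shows up
  ## as NA in the payload columns
  if (nrow(seg) != 1L || is.na(seg$length_bp))
    stop("unknown segment id: ", id)
  if (is.na(seg$sequence))
    stop("segment ", id, " carries no sequence; supply sequences in the ",
         "rGFA or a precomputed divergence table")
  al <- alignment_identity(seg$sequence, ref_window)
  data.table(id = id, identity_frac = al$identity,
             divergence = 1 - al$identity,
             aligned_length = al$aligned_length)
}
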