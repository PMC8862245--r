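## Small shared numeric / bookkeeping helpers.

#' Length-weighted median (N50) of a set of lengths
#'
#' N50 is the length L such that segments of length >= L cover at least half
#' of the total length, computed over lengths sorted in decreasing order.
#'
#' @param lengths numeric vector of positive lengths.
#' @return a single number; `NA` for an empty input.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) return(NA_real_)
  stopifnot(all(lengths > 0))
  srt <- sort(as.numeric(lengths), decreasing = TRUE)
  csum <- cumsum(srt)
  srt[which(csum >= sum(srt) / 2)[1L]]
}

## Flip a +/- orientation character vector.
flip_orient <- function(o) ifelse(o == "+", "-", "+")

## Canonicalise an oriented link (a, oa) -> (b, ob): the reverse traversal
## (b, flip(ob)) -> (a, flip(oa)) denotes the same junction.  Keep whichever
## representation has the lexicographically smaller (id, orient) head so a
## traversal in either direction maps to one key.
canonical_link <- function(from_id, from_orient, to_id, to_orient) {
  head_fwd <- paste0(from_id, from_orient)
  head_rev <- paste0(to_id, flip_orient(to_orient))
  swap <- head_rev < head_fwd |
    (head_rev == head_fwd & paste0(to_id, to_orient) < paste0(from_id, from_orient))
  data.table(
    from_id     = ifelse(swap, to_id, from_id),
    from_orient = ifelse(swap, flip_orient(to_orient), from_orient),
    to_id       = ifelse(swap, from_id, to_id),
    to_orient   = ifelse(swap, flip_orient(from_orient), to_orient)
  )
}

link_key <- function(from_id, from_orient, to_id, to_orient) {
  paste0(from_id, from_orient, ">", to_id, to_orient)
}

## Minimal union-find for transitive-closure clustering (sv merging).
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

## Union pairs (two integer vectors) over n items; returns component labels
## renumbered 1..k in order of first appearance (input-order independent when
## items are pre-sorted by a canonical key).
uf_components <- function(n, a, b) {
  parent <- uf_new(n)
  for (k in seq_along(a)) {
    ra <- uf_find(parent, a[k])
    rb <- uf_find(parent, b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

## Deterministic sub-seed derivation (keeps derived seeds under 2^31).
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
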