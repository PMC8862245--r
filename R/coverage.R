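## Per-sample coverage over the graph: length-normalised segment depths and
## junction traversal counts from GAF path intervals.

#' Compute a per-sample coverage profile from GAF records
#'
#' Aligned bases are attributed to each path member by intersecting the
#' record's `[pstart, pend)` interval with the member's span on the
#' concatenated path; a junction between consecutive path members is counted
#' when the alignment covers at least one base on each side of it, so
#' traversals are orientation-symmetric.  Depth is aligned bases divided by
#' segment length.  `ref_mean` is the length-weighted mean depth over
#' REF_PRIMARY segments: total aligned bases on them over their total
#' length (a simple mean of per-segment depths is available via
#' `ref_mean_mode = "simple"`).
#'
#' @param records data.table from [parse_gaf()].
#' @param g a `pan_graph`.
#' @param sample_id sample identifier.
#' @param kind `"DNA"` or `"RNA"`.
#' @param ref_mean_mode `"weighted"` (default) or `"simple"`.
#' @return a `coverage_profile`: list with `sample_id`, `kind`, `bases` and
#'   `depth` (named numeric over all graph segments), `junctions` (named
#'   counts keyed by canonical link), `ref_mean`.
#' @export
compute_profile <- function(records, g, sample_id, kind = "DNA",
                            ref_mean_mode = c("weighted", "simple")) {
  ref_mean_mode <- match.arg(ref_mean_mode)
  kind <- match.arg(kind, c("DNA", "RNA"))
  segs <- g$segments
  seg_len <- setNames(as.numeric(segs$length_bp), segs$id)

  unknown <- setdiff(unique(unlist(records$path_ids)), segs$id)
  if (length(unknown) > 0L) {
    bad_row <- which(vapply(records$path_ids,
                            function(p) any(p %in% unknown), logical(1)))[1L]
    stop("GAF record ", records$qname[bad_row],
         " references unknown segment(s): ",
         paste(head(unknown, 5L), collapse = ", "))
  }

  bases <- setNames(numeric(length(seg_len)), names(seg_len))
  junctions <- numeric(0)

  if (nrow(records) > 0L) {
    per_rec <- mapply(function(ids, ors, ps, pe) {
      lens <- seg_len[ids]
      cum_end <- cumsum(lens)
      cum_start <- cum_end - lens
      ov <- pmin(pe, cum_end) - pmax(ps, cum_start)
      k <- length(ids)
      jk <- if (k > 1L) {
        c_pos <- cum_end[-k]
        crossed <- ps < c_pos & c_pos < pe
        if (any(crossed)) {
          cl <- canonical_link(ids[-k][crossed], ors[-k][crossed],
                               ids[-1L][crossed], ors[-1L][crossed])
          link_key(cl$from_id, cl$from_orient, cl$to_id, cl$to_orient)
        } else character()
      } else character()
      list(ids = ids[ov > 0], ov = ov[ov > 0], jk = jk)
    }, records$path_ids, records$path_orients, records$pstart, records$pend,
    SIMPLIFY = FALSE)

    base_dt <- data.table(id = unlist(lapply(per_rec, `[[`, "ids")),
                          ov = unlist(lapply(per_rec, `[[`, "ov")))
    if (nrow(base_dt) > 0L) {
      agg <- base_dt[, .(bases = sum(ov)), by = id]
      bases[agg$id] <- agg$bases
    }
    jks <- unlist(lapply(per_rec, `[[`, "jk"))
    if (length(jks) > 0L) {
      jt <- table(jks)
      junctions <- setNames(as.numeric(jt), names(jt))
    }
  }

  depth <- bases / seg_len
  ref_ids <- segs[origin_class == "REF_PRIMARY", id]
  ref_mean <- if (ref_mean_mode == "weighted") {
    sum(bases[ref_ids]) / sum(seg_len[ref_ids])
  } else {
    mean(depth[ref_ids])
  }

  structure(list(sample_id = sample_id, kind = kind, bases = bases,
                 depth = depth, junctions = junctions, ref_mean = ref_mean),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", x$sample_id, "(", x$kind, ")",
      sum(x$bases), "aligned bases, ref_mean =", signif(x$ref_mean, 4), "\n")
  invisible(x)
}

#' Call segment usage at a threshold
#'
#' A segment is used when its depth is at least `theta` times the sample's
#' reference mean depth (inclusive).
#'
#' @param profile a `coverage_profile`.
#' @param theta fraction of `ref_mean` (e.g. 0.05 or 0.10).
#' @return named logical vector over all graph segments.
#' @export
usage_call <- function(profile, theta) {
  if (!is.finite(profile$ref_mean) || profile$ref_mean <= 0)
    stop("ref_mean is zero for sample ", profile$sample_id,
         ": no reads aligned to REF_PRIMARY segments")
  profile$depth >= theta * profile$ref_mean
}

#' Usage matrix over samples
#'
#' @param profiles list of `coverage_profile`s.
#' @param theta usage threshold passed to [usage_call()].
#' @return logical matrix segments x samples.
#' @export
usage_matrix <- function(profiles, theta) {
  stopifnot(length(profiles) >= 1L)
  m <- vapply(profiles, usage_call, theta = theta,
              logical(length(profiles[[1L]]$depth)))
  colnames(m) <- vapply(profiles, `[[`, character(1), "sample_id")
  rownames(m) <- names(profiles[[1L]]$depth)
  m
}

#' Fractions of aligned bases per origin class
#'
#' @param profile a `coverage_profile`.
#' @param g the `pan_graph` the profile was computed on.
#' @return data.table `origin_class`, `bases`, `fraction`; fractions sum to
#'   1 over classes with any aligned bases.
#' @export
origin_fractions <- function(profile, g) {
  total <- sum(profile$bases)
  if (total <= 0) stop("profile has no aligned bases")
  dt <- data.table(id = names(profile$bases), bases = profile$bases)
  dt <- merge(dt, g$segments[, .(id, origin_class)], by = "id")
  out <- dt[, .(bases = sum(bases)), by = origin_class]
  out[, fraction := bases / total]
  setorder(out, origin_class)
  out[]
}

#' Cross-usage of non-reference segments across samples
#'
#' For each sample, aligned bases on non-REF_PRIMARY segments are stratified
#' by the number of samples using each segment at threshold `theta`
#' (stratum 0 = used by nobody at theta).  Per-sample strata sum to that
#' sample's total non-REF_PRIMARY aligned bases.
#'
#' @param profiles list of `coverage_profile`s (>= 2 samples).
#' @param g the `pan_graph`.
#' @param theta usage threshold.
#' @return data.table `sample_id`, `stratum`, `bases`.
#' @export
cross_usage <- function(profiles, g, theta) {
  stopifnot(length(profiles) >= 2L)
  um <- usage_matrix(profiles, theta)
  users <- rowSums(um)
  alt_ids <- g$segments[origin_class != "REF_PRIMARY", id]
  out <- rbindlist(lapply(profiles, function(p) {
    b <- p$bases[alt_ids]
    data.table(sample_id = p$sample_id, stratum = users[alt_ids], bases = b)
  }))
  out <- out[, .(bases = sum(bases)), by = .(sample_id, stratum)]
  setorder(out, sample_id, stratum)
  out[]
}

#' Write a per-sample depth table
#'
#' @param profile a `coverage_profile`.
#' @param g the `pan_graph`.
#' @param theta usage threshold annotated in the table.
#' @param path optional output TSV.
#' @return data.table `id`, `origin_class`, `length_bp`, `depth`, `used`.
#' @export
profile_table <- function(profile, g, theta = 0.05, path = NULL) {
  used <- usage_call(profile, theta)
  dt <- g$segments[, .(id, origin_class, length_bp)]
  dt[, depth := profile$depth[id]]
  dt[, used := used[id]]
  if (!is.null(path)) fwrite(dt, path, sep = "\t")
  dt[]
}
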