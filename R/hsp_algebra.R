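#' Merge 1-based inclusive intervals into maximal disjoint intervals
#'
#' Computes the union of the input positions as a sorted list of maximal
#' disjoint intervals. Adjacent intervals (`end + 1 == next start`) are
#' coalesced. This is how overlapping HSPs of one query-subject pair are
#' collapsed before a coverage ratio is computed.
#'
#' @param starts,ends Integer vectors of equal length; `starts[i] <=
#'   ends[i]` is required.
#' @return A tibble with columns `start` and `end`, sorted, pairwise
#'   disjoint, plus an attribute-free `covered_length` obtainable as
#'   `sum(end - start + 1)`.
#' @examples
#' merge_intervals(c(1, 40), c(50, 100)) # one interval 1..100
#' @export
merge_intervals <- function(starts, ends) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  bad <- which(starts > ends)
  if (length(bad)) {
    abort(paste0("interval start > end: (", starts[bad[1L]], ", ",
                 ends[bad[1L]], ")"))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = as.integer(starts),
                                         end = as.integer(ends)))
  tibble(start = IRanges::start(ir), end = IRanges::end(ir))
}

#' Merged-HSP coverage of one query-subject pair
#'
#' Projects every HSP of a single query-subject pair onto the chosen axis,
#' merges the projected intervals, and reports the covered fraction of that
#' axis. With `merged = FALSE` the raw sum of HSP lengths is used instead
#' of the merged union (a ratio that can exceed 1; kept for comparison with
#' summation-style coverage, not used by default).
#'
#' @param hsps Hit tibble whose rows all share one `(query_id, subject_id)`
#'   pair.
#' @param axis `"query"` or `"subject"`: which sequence the coverage is
#'   measured on.
#' @param axis_length Length of that sequence (bp or aa, matching the
#'   search type).
#' @param merged Use merged intervals (default) or the raw sum of HSP
#'   spans.
#' @return A list with `query_id`, `subject_id`, `merged_intervals`
#'   (tibble), `covered_length`, `axis_length`, and `ratio`.
#' @export
pair_coverage <- function(hsps, axis = c("query", "subject"), axis_length,
                          merged = TRUE) {
  axis <- match.arg(axis)
  stopifnot(axis_length >= 1)
  if (nrow(hsps) > 0L) {
    if (length(unique(hsps$query_id)) > 1L ||
        length(unique(hsps$subject_id)) > 1L) {
      abort("pair_coverage: rows mix more than one query-subject pair")
    }
  }
  if (axis == "query") {
    starts <- hsps$q_start; ends <- hsps$q_end
  } else {
    starts <- hsps$s_start; ends <- hsps$s_end
  }
  iv <- merge_intervals(starts, ends)
  covered <- if (merged) {
    sum(iv$end - iv$start + 1L)
  } else {
    sum(ends - starts + 1L)
  }
  list(
    query_id = if (nrow(hsps)) hsps$query_id[1L] else NA_character_,
    subject_id = if (nrow(hsps)) hsps$subject_id[1L] else NA_character_,
    merged_intervals = iv,
    covered_length = as.integer(covered),
    axis_length = as.integer(axis_length),
    ratio = covered / axis_length
  )
}

#' Seed-candidate pre-filters on a protein-space hit
#'
#' The two filters applied to a translated (contig vs reference protein)
#' search before a contig may seed the integration: HSPs shorter than
#' `min_hsp_aa` amino acids are discarded first, then the surviving HSPs
#' must cover at least `min_ratio` of the reference protein after merging.
#' The coverage comparison is inclusive (exactly 50\% passes).
#'
#' @param hsps Hit tibble for one contig-protein pair (subject = protein,
#'   coordinates in aa).
#' @param subject_length Reference protein length (aa).
#' @param min_ratio Minimum merged subject coverage (default 0.5).
#' @param min_hsp_aa Minimum HSP length in aa (default 20).
#' @param merged Coverage from merged intervals (default) or raw HSP-length
#'   sum.
#' @return Logical scalar.
#' @export
passes_seed_filters <- function(hsps, subject_length, min_ratio = 0.5,
                                min_hsp_aa = 20, merged = TRUE) {
  keep <- hsps[hsps$alignment_length >= min_hsp_aa, , drop = FALSE]
  if (nrow(keep) == 0L) return(FALSE)
  cov <- pair_coverage(keep, axis = "subject", axis_length = subject_length,
                       merged = merged)
  cov$ratio >= min_ratio
}
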