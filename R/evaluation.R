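#' Percentage with two-decimal half-up rounding
#'
#' `100 * count / denominator`, rounded half-up to two decimals — the
#' rounding used by the published coverage tables (base `round()` would
#' round half to even).
#'
#' @param count Non-negative count, `count <= denominator`.
#' @param denominator Positive denominator.
#' @return Numeric with two decimals.
#' @examples
#' percentage(45612, 56399) # 80.87
#' @export
percentage <- function(count, denominator) {
  stopifnot(all(denominator > 0), all(count >= 0), all(count <= denominator))
  floor(100 * count / denominator * 100 + 0.5) / 100
}

# Per-sequence best-partner coverage on one axis of a hit table.
# Returns a named vector: for each distinct id on `axis`, the maximum over
# partners of the merged per-pair coverage of that sequence.
best_partner_coverage <- function(hits, axis = c("query", "subject"),
                                  lengths, union_partners = FALSE) {
  axis <- match.arg(axis)
  if (nrow(hits) == 0L) return(setNames(numeric(0), character(0)))
  id_col <- if (axis == "query") "query_id" else "subject_id"
  st <- if (axis == "query") "q_start" else "s_start"
  en <- if (axis == "query") "q_end" else "s_end"
  missing <- setdiff(unique(hits[[id_col]]), names(lengths))
  if (length(missing)) {
    abort(paste0("no length known for: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (union_partners) {
    cov <- hits %>%
      group_by(id = .data[[id_col]]) %>%
      summarise(covered = merged_span_length(.data[[st]], .data[[en]]),
                .groups = "drop")
  } else {
    cov <- hits %>%
      group_by(id = .data[[id_col]], .data$query_id, .data$subject_id) %>%
      summarise(covered = merged_span_length(.data[[st]], .data[[en]]),
                .groups = "drop") %>%
      group_by(.data$id) %>%
      summarise(covered = max(.data$covered), .groups = "drop")
  }
  setNames(cov$covered / unname(lengths[cov$id]), cov$id)
}

#' Mutual coverage between two transcript sets
#'
#' Computes one row of a coverage table between a transcript set A and a
#' reference set B. HSPs of each query-subject pair are merged, each
#' sequence's coverage is the best merged per-pair coverage over its
#' partners, and a sequence counts as covered only when that coverage is
#' strictly above `threshold` of its total length. "covered_by" counts B
#' sequences covered by A; "cover_to" counts A sequences covered by B.
#' Denominators are the full set sizes and percentages use two-decimal
#' half-up rounding.
#'
#' @param hits_a_vs_b Hit tibble with set-A queries and set-B subjects.
#' @param hits_b_vs_a Hit tibble with set-B queries and set-A subjects
#'   (may be an empty table when only one direction was searched; both
#'   directions contribute evidence for both counts).
#' @param lengths_a,lengths_b Named length vectors covering every id of
#'   each set (their lengths define the denominators).
#' @param threshold Strict coverage cutoff in (0, 1]; default 0.75.
#' @param source_name Label for the output row.
#' @param union_partners Pool intervals across partners before measuring
#'   coverage instead of taking the best single partner (comparison mode;
#'   default off).
#' @return A one-row tibble: `source_name`, `covered_by_count`,
#'   `covered_by_pct`, `cover_to_count`, `cover_to_pct`,
#'   `denominator_source`, `denominator_target`, `threshold`.
#' @export
mutual_coverage <- function(hits_a_vs_b, hits_b_vs_a, lengths_a, lengths_b,
                            threshold = 0.75, source_name = "setB",
                            union_partners = FALSE) {
  stopifnot(threshold > 0, threshold <= 1)
  cov_b <- pmax_named(
    best_partner_coverage(hits_a_vs_b, "subject", lengths_b, union_partners),
    best_partner_coverage(hits_b_vs_a, "query", lengths_b, union_partners)
  )
  cov_a <- pmax_named(
    best_partner_coverage(hits_a_vs_b, "query", lengths_a, union_partners),
    best_partner_coverage(hits_b_vs_a, "subject", lengths_a, union_partners)
  )
  covered_by <- sum(cov_b > threshold)
  cover_to <- sum(cov_a > threshold)
  tibble(
    source_name = source_name,
    covered_by_count = covered_by,
    covered_by_pct = percentage(covered_by, length(lengths_b)),
    cover_to_count = cover_to,
    cover_to_pct = percentage(cover_to, length(lengths_a)),
    denominator_source = length(lengths_b),
    denominator_target = length(lengths_a),
    threshold = threshold
  )
}

pmax_named <- function(x, y) {
  ids <- union(names(x), names(y))
  out <- setNames(numeric(length(ids)), ids)
  out[names(x)] <- pmax(out[names(x)], x)
  out[names(y)] <- pmax(out[names(y)], y)
  out
}

#' Read-mapping rate from pre-counted totals
#'
#' One minus the unmapped fraction: `1 - unmapped / total`.
#'
#' @param total_reads Positive integer vector of total read counts.
#' @param unmapped_reads Integer vector, `0 <= unmapped <= total`.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' mapping_rate(100, 8) # 0.92
#' @export
mapping_rate <- function(total_reads, unmapped_reads) {
  stopifnot(all(total_reads > 0))
  if (any(unmapped_reads < 0 | unmapped_reads > total_reads)) {
    abort("unmapped_reads must lie in [0, total_reads]")
  }
  1 - unmapped_reads / total_reads
}
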