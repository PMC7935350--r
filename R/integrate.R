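merged_span_length <- function(starts, ends) {
  iv <- merge_intervals(starts, ends)
  sum(iv$end - iv$start + 1L)
}

# Collapse a hit table to one row per (query, subject) pair, with the
# pair's best bit score, best e-value, and merged subject coverage.
# When `apply_filters` is TRUE the two seed pre-filters act: rows shorter
# than `min_hsp` are dropped first, then pairs with merged subject
# coverage below `min_ratio` are dropped.
pair_stats <- function(hits, subject_lengths, min_ratio = 0.5, min_hsp = 20,
                       apply_filters = TRUE) {
  if (apply_filters) {
    hits <- hits[hits$alignment_length >= min_hsp, , drop = FALSE]
  }
  if (nrow(hits) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  bit_score = numeric(), evalue = numeric(),
                  coverage = numeric()))
  }
  missing <- setdiff(unique(hits$subject_id), names(subject_lengths))
  if (length(missing)) {
    abort(paste0("no length known for subject(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  out <- hits %>%
    group_by(.data$query_id, .data$subject_id) %>%
    summarise(
      bit_score = max(.data$bit_score),
      evalue = min(.data$evalue),
      covered = merged_span_length(.data$s_start, .data$s_end),
      .groups = "drop"
    ) %>%
    mutate(coverage = .data$covered /
             unname(subject_lengths[.data$subject_id])) %>%
    select(-"covered")
  if (apply_filters) out <- filter(out, .data$coverage >= min_ratio)
  out
}

# Deterministic best-partner pick: highest bit score, then lowest e-value,
# then largest merged subject coverage, then lexicographically smallest
# partner id. `group` is the column to pick within, `partner` the column
# being ranked.
best_partner <- function(pairs, group, partner) {
  pairs %>%
    arrange(desc(.data$bit_score), .data$evalue, desc(.data$coverage),
            .data[[partner]]) %>%
    group_by(.data[[group]]) %>%
    slice(1L) %>%
    ungroup()
}

#' Select reciprocal-best-hit seed contigs per library
#'
#' Module-1 of the semi-manual integration. For every library, translated
#' contig-vs-reference hits are reduced to one candidate pair per
#' (contig, reference gene) after the seed pre-filters
#' ([passes_seed_filters()] semantics: HSPs >= `min_hsp_aa` aa, merged
#' subject coverage >= `min_subject_coverage`). Each reference gene is then
#' linked to the single contig with the highest bit score (ties: lower
#' e-value, larger merged subject coverage, lexicographically smaller
#' contig id), and the link is kept as a seed only when it is reciprocal:
#' the reverse (reference-vs-contig) search must rank that gene as the
#' contig's best partner under the same tie-break.
#'
#' @param forward_hits Hit tibble of translated contig (query) vs reference
#'   protein (subject) searches, with a `library_id` column.
#' @param reverse_hits Hit tibble of reference protein (query) vs contig
#'   (subject) searches; subject coordinates in bp on the contig.
#' @param reference_lengths Named numeric vector of reference protein
#'   lengths (aa).
#' @param contig_lengths Named numeric vector of contig lengths (bp),
#'   required when `filter_reverse = TRUE`.
#' @param thresholds An [integration_thresholds()] list.
#' @param filter_reverse Apply the same two pre-filters to the reverse
#'   direction (default). `FALSE` ranks reverse partners from the raw
#'   table.
#' @return A tibble with columns `reference_gene_id`, `library_id`,
#'   `contig_id`, `bit_score`, `reciprocal`. Seeds are the rows with
#'   `reciprocal == TRUE` (kept in the output so near-misses can be
#'   audited).
#' @export
select_seeds <- function(forward_hits, reverse_hits, reference_lengths,
                         contig_lengths = NULL,
                         thresholds = integration_thresholds(),
                         filter_reverse = TRUE) {
  if (nrow(forward_hits) == 0L) {
    warn("empty forward hit table: no seeds")
    return(tibble(reference_gene_id = character(), library_id = character(),
                  contig_id = character(), bit_score = numeric(),
                  reciprocal = logical()))
  }
  stopifnot("library_id" %in% names(forward_hits))
  if (filter_reverse && is.null(contig_lengths)) {
    abort("contig_lengths is required when filter_reverse = TRUE")
  }
  out <- lapply(split(forward_hits, forward_hits$library_id), function(fh) {
    lib <- fh$library_id[1L]
    fwd <- pair_stats(fh, reference_lengths,
                      min_ratio = thresholds$min_subject_coverage,
                      min_hsp = thresholds$min_hsp_aa)
    if (nrow(fwd) == 0L) return(NULL)
    best_contig <- best_partner(fwd, group = "subject_id",
                                partner = "query_id")
    # reverse direction, restricted to this library's contigs
    rh <- reverse_hits[reverse_hits$subject_id %in% fh$query_id, ,
                       drop = FALSE]
    rev_pairs <- pair_stats(rh, if (filter_reverse) contig_lengths else
                              setNames(rep(1, length(unique(rh$subject_id))),
                                       unique(rh$subject_id)),
                            min_ratio = thresholds$min_subject_coverage,
                            min_hsp = thresholds$min_hsp_aa,
                            apply_filters = filter_reverse)
    best_gene <- best_partner(rev_pairs, group = "subject_id",
                              partner = "query_id") %>%
      select(contig_id = "subject_id", best_gene = "query_id")
    best_contig %>%
      rename(reference_gene_id = "subject_id", contig_id = "query_id") %>%
      left_join(best_gene, by = "contig_id") %>%
      mutate(
        library_id = lib,
        reciprocal = !is.na(.data$best_gene) &
          .data$best_gene == .data$reference_gene_id
      ) %>%
      select("reference_gene_id", "library_id", "contig_id", "bit_score",
             "reciprocal")
  })
  out <- bind_rows(out)
  if (nrow(out) == 0L) {
    return(tibble(reference_gene_id = character(), library_id = character(),
                  contig_id = character(), bit_score = numeric(),
                  reciprocal = logical()))
  }
  arrange(out, .data$reference_gene_id, .data$library_id)
}

#' Extend seeds to paralog candidates
#'
#' Module-2 "extend": seeds are used as nucleotide queries against all
#' libraries (including the seed's own) with no hit filtering. The
#' candidate set is the union of every subject contig appearing in the hit
#' table plus the seeds themselves.
#'
#' @param seeds Tibble with `library_id`, `contig_id` (reciprocal seeds
#'   only).
#' @param extend_hits Hit tibble of seed (query) vs all-library contig
#'   (subject) searches.
#' @param contigs Contig tibble resolving every contig id to its library;
#'   contig ids must be globally unique across libraries.
#' @return A tibble of distinct candidates (`library_id`, `contig_id`).
#' @export
extend_paralogs <- function(seeds, extend_hits, contigs) {
  if (anyDuplicated(contigs$contig_id)) {
    abort("contig ids must be globally unique across libraries")
  }
  subj <- unique(extend_hits$subject_id)
  missing <- setdiff(subj, contigs$contig_id)
  if (length(missing)) {
    abort(paste0("hit subjects absent from contig table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  hit_part <- contigs[contigs$contig_id %in% subj,
                      c("library_id", "contig_id")]
  distinct(bind_rows(hit_part, seeds[, c("library_id", "contig_id")])) %>%
    arrange(.data$library_id, .data$contig_id)
}

#' Cluster near-identical candidates across libraries ("concentrate")
#'
#' Module-2 "concentrate": builds a graph with an edge between two
#' candidate contigs whenever their global edit distance (mismatches plus
#' gaps) is at most `concentrate_tolerance_bp`, takes connected components
#' (single linkage, so the tolerance relation is closed transitively even
#' though it is not itself transitive), and picks the longest member of
#' each component as its representative (ties: lexicographically smallest
#' `(library_id, contig_id)`). Components spanning fewer than
#' `min_library_support` distinct libraries are flagged `retained = FALSE`.
#'
#' Candidates whose lengths differ by more than the tolerance cannot be
#' within distance, so only length-compatible pairs are scored.
#'
#' @param candidates Tibble with `library_id`, `contig_id`, `sequence`,
#'   `length`; contig ids globally unique.
#' @param thresholds An [integration_thresholds()] list.
#' @return A tibble of clusters: `cluster_id`, `members` (list column of
#'   tibbles), `representative_library`, `representative_contig`,
#'   `n_members`, `library_support`, `retained`.
#' @export
concentrate <- function(candidates, thresholds = integration_thresholds()) {
  tol <- thresholds$concentrate_tolerance_bp
  n <- nrow(candidates)
  if (n == 0L) {
    return(tibble(cluster_id = character(), members = list(),
                  representative_library = character(),
                  representative_contig = character(),
                  n_members = integer(), library_support = integer(),
                  retained = logical()))
  }
  if (anyDuplicated(candidates$contig_id)) {
    abort("candidate contig ids must be globally unique")
  }
  ord <- order(candidates$length, candidates$contig_id)
  cand <- candidates[ord, , drop = FALSE]
  # enumerate length-compatible pairs from the sorted order
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && cand$length[j] - cand$length[i] <= tol) {
      ii <- c(ii, i); jj <- c(jj, j)
      j <- j + 1L
    }
  }
  edges <- integer(0)
  if (length(ii)) {
    d <- bounded_edit_distance(cand$sequence[ii], cand$sequence[jj], k = tol)
    hit <- !is.na(d)
    edges <- rbind(ii[hit], jj[hit])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership
  mk <- split(seq_len(n), comp)
  clusters <- lapply(mk, function(idx) {
    mem <- cand[idx, c("library_id", "contig_id", "length")]
    mem <- arrange(mem, .data$library_id, .data$contig_id)
    rep_row <- mem %>%
      arrange(desc(.data$length), .data$library_id, .data$contig_id) %>%
      slice(1L)
    tibble(
      members = list(mem[, c("library_id", "contig_id")]),
      representative_library = rep_row$library_id,
      representative_contig = rep_row$contig_id,
      n_members = nrow(mem),
      library_support = length(unique(mem$library_id)),
      first_key = paste(mem$library_id[1L], mem$contig_id[1L])
    )
  })
  out <- bind_rows(clusters) %>%
    arrange(.data$first_key) %>%
    mutate(
      cluster_id = sprintf("CL%05d", row_number()),
      retained = .data$library_support >= thresholds$min_library_support
    ) %>%
    select("cluster_id", "members", "representative_library",
           "representative_contig", "n_members", "library_support",
           "retained")
  out
}

#' Rescue seed singletons dropped by the library-support rule
#'
#' Module-2 final step: a seed contig that belongs to no retained cluster
#' (its component failed the >= 2-library rule, typically because it has no
#' homolog in any other library) is added back to the integrated set.
#' Non-seed singletons stay dropped.
#'
#' @param seeds Tibble with `library_id`, `contig_id` of reciprocal seeds.
#' @param clusters Output of [concentrate()].
#' @return Tibble (`library_id`, `contig_id`) of rescued seeds.
#' @export
rescue_singletons <- function(seeds, clusters) {
  retained_members <- bind_rows(clusters$members[clusters$retained])
  if (nrow(retained_members) == 0L) {
    retained_members <- tibble(library_id = character(),
                               contig_id = character())
  }
  seeds %>%
    distinct(.data$library_id, .data$contig_id) %>%
    dplyr::anti_join(retained_members, by = c("library_id", "contig_id")) %>%
    arrange(.data$library_id, .data$contig_id)
}

#' Partition contigs by the taxonomy of their best database hit
#'
#' Module-3 contamination filter. Every contig is classified by the
#' superkingdom of its best hit (highest bit score; ties broken by lower
#' e-value then lexicographically smallest subject id) against a reference
#' protein database with taxonomy labels. Under `policy = "module3"`
#' contigs matching Eukaryota, unclassified subjects, or nothing at all are
#' kept and only confident non-eukaryote matches are discarded; under
#' `policy = "strict_eukaryote"` only contigs whose best hit is Eukaryota
#' survive.
#'
#' @param contig_ids Character vector of contig ids to partition.
#' @param best_hits Hit tibble of contig (query) vs database subject.
#' @param taxonomy_map Tibble from [read_taxonomy_map()].
#' @param policy `"module3"` or `"strict_eukaryote"`.
#' @return A list with `kept` and `discarded` (character vectors forming a
#'   partition of `contig_ids`) and `classification` (tibble with
#'   `contig_id`, `subject_id`, `superkingdom`, `kept`).
#' @export
taxonomy_filter <- function(contig_ids, best_hits, taxonomy_map,
                            policy = c("module3", "strict_eukaryote")) {
  policy <- match.arg(policy)
  hits <- best_hits[best_hits$query_id %in% contig_ids, , drop = FALSE]
  best <- hits %>%
    arrange(desc(.data$bit_score), .data$evalue, .data$subject_id) %>%
    group_by(.data$query_id) %>%
    slice(1L) %>%
    ungroup() %>%
    select(contig_id = "query_id", "subject_id")
  unknown <- setdiff(best$subject_id, taxonomy_map$subject_id)
  if (length(unknown)) {
    warn(paste0(length(unknown),
                " hit subject(s) missing from the taxonomy map; ",
                "treated as unclassified"))
  }
  cls <- tibble(contig_id = contig_ids) %>%
    left_join(best, by = "contig_id") %>%
    left_join(taxonomy_map, by = "subject_id") %>%
    mutate(superkingdom = dplyr::case_when(
      is.na(.data$subject_id) ~ "no_hit",
      is.na(.data$superkingdom) ~ "unclassified",
      TRUE ~ .data$superkingdom
    ))
  keep_set <- if (policy == "module3") {
    c("Eukaryota", "unclassified", "no_hit")
  } else {
    "Eukaryota"
  }
  cls$kept <- cls$superkingdom %in% keep_set
  list(
    kept = cls$contig_id[cls$kept],
    discarded = cls$contig_id[!cls$kept],
    classification = cls
  )
}

#' Merge the semi-manual and automatic contig sets
#'
#' Homology-based union of two integrated sets. A contig of set A is
#' collapsed into a contig of set B when a cross-hit between them reaches
#' `min_identity` percent identity and the merged hit intervals cover at
#' least `min_containment` of the shorter sequence; the surviving record
#' takes provenance `"both"`. The defaults (100\% identity, full
#' containment) collapse only exact duplicates/containments.
#'
#' @param semi_manual,automatic Contig tibbles (`contig_id`, `sequence`,
#'   `length`); ids must not overlap between the sets.
#' @param cross_hits Hit tibble of semi-manual (query) vs automatic
#'   (subject) contigs.
#' @param min_identity Minimum percent identity of contributing HSPs.
#' @param min_containment Minimum merged coverage of the shorter sequence.
#' @return A contig tibble with a `provenance` column in
#'   `{semi_manual, automatic, both}`; `nrow == |A| + |B| - collapsed`.
#' @export
merge_sets <- function(semi_manual, automatic, cross_hits,
                       min_identity = 100, min_containment = 1.0) {
  overlap <- intersect(semi_manual$contig_id, automatic$contig_id)
  if (length(overlap)) {
    abort(paste0("contig ids shared between the two sets: ",
                 paste(head(overlap, 5), collapse = ", ")))
  }
  semi_len <- setNames(semi_manual$length, semi_manual$contig_id)
  auto_len <- setNames(automatic$length, automatic$contig_id)
  hits <- cross_hits[cross_hits$percent_identity >= min_identity &
                       cross_hits$query_id %in% names(semi_len) &
                       cross_hits$subject_id %in% names(auto_len), ,
                     drop = FALSE]
  collapsed <- character(0)
  if (nrow(hits)) {
    pair_cov <- hits %>%
      group_by(.data$query_id, .data$subject_id) %>%
      summarise(
        q_cov = merged_span_length(.data$q_start, .data$q_end),
        s_cov = merged_span_length(.data$s_start, .data$s_end),
        .groups = "drop"
      ) %>%
      mutate(
        short_len = pmin(unname(semi_len[.data$query_id]),
                         unname(auto_len[.data$subject_id])),
        short_cov = ifelse(unname(semi_len[.data$query_id]) <=
                             unname(auto_len[.data$subject_id]),
                           .data$q_cov, .data$s_cov),
        contained = .data$short_cov >= min_containment * .data$short_len
      )
    collapsed_pairs <- filter(pair_cov, .data$contained)
    collapsed <- unique(collapsed_pairs$query_id)
    absorbing <- unique(collapsed_pairs$subject_id)
  } else {
    absorbing <- character(0)
  }
  semi_keep <- semi_manual[!semi_manual$contig_id %in% collapsed, ,
                           drop = FALSE]
  semi_keep$provenance <- "semi_manual"
  auto_out <- automatic
  auto_out$provenance <- ifelse(auto_out$contig_id %in% absorbing,
                                "both", "automatic")
  bind_rows(semi_keep, auto_out) %>% arrange(.data$contig_id)
}

#' Group contigs into isoform clusters from a self-search
#'
#' Two contigs of the integrated set are linked as isoforms when some
#' self-search HSP between them has percent identity strictly above
#' `isoform_min_identity_pct` and alignment length strictly above
#' `isoform_min_hsp_bp` (self-pairs are ignored). Isoform groups are the
#' connected components of size >= 2; each reports its longest member as
#' representative.
#'
#' @param contigs Contig tibble of the integrated set (`contig_id`,
#'   `length`).
#' @param self_hits Hit tibble of the set searched against itself (the
#'   search should use a minimum word/seed size of
#'   `isoform_word_size_bp`).
#' @param thresholds An [integration_thresholds()] list.
#' @return A tibble with `isoform_group`, `contig_id`, `representative`.
#' @export
detect_isoforms <- function(contigs, self_hits,
                            thresholds = integration_thresholds()) {
  ids <- contigs$contig_id
  e <- self_hits[self_hits$query_id != self_hits$subject_id &
                   self_hits$percent_identity >
                     thresholds$isoform_min_identity_pct &
                   self_hits$alignment_length > thresholds$isoform_min_hsp_bp &
                   self_hits$query_id %in% ids &
                   self_hits$subject_id %in% ids, , drop = FALSE]
  if (nrow(e) == 0L) {
    return(tibble(isoform_group = character(), contig_id = character(),
                  representative = character()))
  }
  g <- igraph::graph_from_data_frame(
    distinct(e[, c("query_id", "subject_id")]),
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)$membership
  lens <- setNames(contigs$length, contigs$contig_id)
  groups <- split(names(comp), comp)
  groups <- Filter(function(m) length(m) >= 2L, groups)
  if (length(groups) == 0L) {
    return(tibble(isoform_group = character(), contig_id = character(),
                  representative = character()))
  }
  groups <- groups[order(vapply(groups, function(m) sort(m)[1L],
                                character(1)))]
  bind_rows(lapply(seq_along(groups), function(i) {
    m <- sort(groups[[i]])
    rep_id <- m[order(-lens[m], m)][1L]
    tibble(isoform_group = sprintf("ISO%05d", i), contig_id = m,
           representative = rep_id)
  }))
}

#' Run the full integration pipeline
#'
#' Chains the semi-manual stages: reciprocal-best-hit seed selection,
#' paralog extension, redundancy clustering with singleton rescue, the
#' module-3 taxonomy filter, an optional homology merge with an
#' automatically integrated set followed by a final taxonomy filter, and
#' isoform grouping. Every stage is deterministic; the returned report
#' lists the contig count entering and leaving each filter.
#'
#' @param contigs All-library contig tibble (globally unique ids).
#' @param reference_lengths Named vector of reference protein lengths (aa).
#' @param forward_hits,reverse_hits,extend_hits,nr_hits,self_hits Hit
#'   tibbles for the translated seed search (with `library_id`), its
#'   reverse, the seed-vs-libraries nucleotide search, the
#'   taxonomy-database search, and the integrated-set self-search.
#' @param taxonomy_map Tibble from [read_taxonomy_map()].
#' @param thresholds An [integration_thresholds()] list.
#' @param automatic Optional automatic-pipeline contig tibble.
#' @param cross_hits Cross-hit table (semi-manual vs automatic), required
#'   with `automatic`.
#' @param final_policy Taxonomy policy for the post-merge filter
#'   (`"module3"` keeps unclassified and no-hit contigs,
#'   `"strict_eukaryote"` does not).
#' @return A list: `seeds`, `candidates`, `clusters`, `rescued`,
#'   `semi_manual`, `taxonomy`, `integrated` (final contig tibble with
#'   provenance), `isoforms`, and `report` (stage-count tibble).
#' @export
integrate_all <- function(contigs, reference_lengths, forward_hits,
                          reverse_hits, extend_hits, nr_hits, taxonomy_map,
                          self_hits = empty_hit_table(),
                          thresholds = integration_thresholds(),
                          automatic = NULL, cross_hits = NULL,
                          final_policy = c("module3", "strict_eukaryote")) {
  final_policy <- match.arg(final_policy)
  if (anyDuplicated(contigs$contig_id)) {
    abort("contig ids must be globally unique across libraries")
  }
  contig_lengths <- setNames(contigs$length, contigs$contig_id)

  assignments <- select_seeds(forward_hits, reverse_hits, reference_lengths,
                              contig_lengths, thresholds)
  seeds <- filter(assignments, .data$reciprocal)
  candidates <- extend_paralogs(seeds, extend_hits, contigs)
  cand_seq <- left_join(candidates,
                        contigs[, c("contig_id", "sequence", "length")],
                        by = "contig_id")
  clusters <- concentrate(cand_seq, thresholds)
  rescued <- rescue_singletons(seeds[, c("library_id", "contig_id")],
                               clusters)
  reps <- clusters %>%
    filter(.data$retained) %>%
    select(library_id = "representative_library",
           contig_id = "representative_contig")
  semi_ids <- unique(c(reps$contig_id, rescued$contig_id))
  tax <- taxonomy_filter(sort(semi_ids), nr_hits, taxonomy_map,
                         policy = "module3")
  semi_set <- contigs[match(tax$kept, contigs$contig_id), , drop = FALSE]

  if (!is.null(automatic)) {
    if (is.null(cross_hits)) {
      abort("cross_hits is required when an automatic set is supplied")
    }
    merged <- merge_sets(semi_set, automatic, cross_hits)
    final_tax <- taxonomy_filter(merged$contig_id, nr_hits, taxonomy_map,
                                 policy = final_policy)
    integrated <- merged[merged$contig_id %in% final_tax$kept, , drop = FALSE]
  } else {
    merged <- NULL
    integrated <- semi_set
    integrated$provenance <- "semi_manual"
  }
  isoforms <- detect_isoforms(integrated, self_hits, thresholds)

  report <- tibble(
    stage = c("seed_assignments", "seeds", "candidates", "clusters",
              "clusters_retained", "rescued", "semi_manual_pre_taxonomy",
              "semi_manual_kept", "semi_manual_discarded", "integrated",
              "isoform_groups"),
    count = c(nrow(assignments), nrow(seeds), nrow(candidates),
              nrow(clusters), sum(clusters$retained), nrow(rescued),
              length(semi_ids), length(tax$kept), length(tax$discarded),
              nrow(integrated), length(unique(isoforms$isoform_group)))
  )
  list(seeds = seeds, candidates = candidates, clusters = clusters,
       rescued = rescued, semi_manual = semi_set, taxonomy = tax,
       merged = merged, integrated = integrated, isoforms = isoforms,
       report = report)
}
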