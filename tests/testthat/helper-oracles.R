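# Independent oracles and small constructors used across the suite.

# Full-matrix Levenshtein distance via base R's generalized edit distance.
lev_oracle <- function(a, b) {
  as.integer(adist(a, b))
}

# Per-position boolean coverage oracle: fraction of axis positions touched
# by any interval.
cov_oracle <- function(starts, ends, axis_length) {
  hit <- logical(axis_length)
  for (i in seq_along(starts)) {
    hit[starts[i]:min(ends[i], axis_length)] <- TRUE
  }
  sum(hit) / axis_length
}

# Build a hit tibble row-by-row with sensible defaults.
make_hits <- function(query_id, subject_id, percent_identity = 99,
                      alignment_length = 100L, mismatches = 0L,
                      gap_opens = 0L, q_start = 1L, q_end = 100L,
                      s_start = 1L, s_end = 100L, evalue = 1e-50,
                      bit_score = 200, s_strand = "+") {
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    percent_identity = percent_identity,
    alignment_length = as.integer(alignment_length),
    mismatches = as.integer(mismatches), gap_opens = as.integer(gap_opens),
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    evalue = evalue, bit_score = bit_score, s_strand = s_strand
  )
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random one-library forward/reverse hit-table pair for RBH testing.
random_rbh_tables <- function(n_genes, n_contigs) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  contigs <- sprintf("C%02d", seq_len(n_contigs))
  ref_len <- setNames(sample(40:100, n_genes, replace = TRUE), genes)
  ctg_len <- setNames(sample(300:900, n_contigs, replace = TRUE), contigs)
  rand_rows <- function(qids, sids, slen) {
    n <- sample(5:25, 1)
    q <- sample(qids, n, replace = TRUE)
    s <- sample(sids, n, replace = TRUE)
    alen <- sample(10:80, n, replace = TRUE)
    span <- pmax(1L, round(slen[s] * runif(n, 0.2, 1)))
    st <- vapply(slen[s] - span + 1L,
                 function(m) sample.int(max(m, 1L), 1), integer(1))
    make_hits(q, s,
              percent_identity = round(runif(n, 60, 100), 1),
              alignment_length = alen,
              q_start = 1L, q_end = alen,
              s_start = st, s_end = st + span - 1L,
              evalue = sample(c(1e-80, 1e-50, 1e-20), n, replace = TRUE),
              bit_score = sample(seq(50, 300, by = 25), n, replace = TRUE))
  }
  list(
    forward = dplyr::mutate(rand_rows(contigs, genes, ref_len),
                            library_id = "L1"),
    reverse = rand_rows(genes, contigs, ctg_len),
    ref_len = ref_len, ctg_len = ctg_len
  )
}

# Plain-loop RBH enumeration: filters, per-partner best with the
# documented tie-break chain, reciprocity.
rbh_oracle <- function(forward, reverse, ref_len, ctg_len,
                       min_ratio = 0.5, min_hsp = 20) {
  pair_best <- function(hits, slen) {
    hits <- hits[hits$alignment_length >= min_hsp, , drop = FALSE]
    out <- list()
    for (q in unique(hits$query_id)) {
      for (s in unique(hits$subject_id[hits$query_id == q])) {
        rows <- hits[hits$query_id == q & hits$subject_id == s, ]
        if (nrow(rows) == 0) next
        cov <- cov_oracle(rows$s_start, rows$s_end, slen[s])
        if (cov < min_ratio) next
        out[[paste(q, s)]] <- data.frame(
          query = q, subject = s, bit = max(rows$bit_score),
          evalue = min(rows$evalue), cov = cov
        )
      }
    }
    do.call(rbind, out)
  }
  argbest <- function(df, group_col, partner_col) {
    res <- list()
    for (g in unique(df[[group_col]])) {
      rows <- df[df[[group_col]] == g, ]
      rows <- rows[order(-rows$bit, rows$evalue, -rows$cov,
                         rows[[partner_col]]), ]
      res[[g]] <- rows[1, partner_col]
    }
    res
  }
  fwd <- pair_best(forward, ref_len)
  rev <- pair_best(reverse, ctg_len)
  if (is.null(fwd)) return(setNames(character(0), character(0)))
  best_contig <- argbest(fwd, "subject", "query")   # per gene
  best_gene <- if (is.null(rev)) list() else argbest(rev, "subject", "query")
  seeds <- setNames(character(0), character(0))
  for (g in names(best_contig)) {
    ctg <- best_contig[[g]]
    bg <- best_gene[[ctg]]
    if (!is.null(bg) && identical(bg, g)) {
      seeds[g] <- ctg
    }
  }
  seeds
}

# Exhaustive bitmask oracle on a logical presence matrix
# (accessions x sites).
bitmask_oracle <- function(mat, include) {
  universe <- rownames(mat)
  excl <- setdiff(universe, include)
  keep <- apply(mat, 2, function(col) {
    all(col[include]) && !any(col[excl])
  })
  sort(colnames(mat)[keep])
}
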