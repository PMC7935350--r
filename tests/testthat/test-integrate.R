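ref_len1 <- c(G1 = 100)
ctg_len2 <- c(c1 = 600, c2 = 600)

test_that("seed selection picks the best-scoring reciprocal contig", {
  fwd <- make_hits(c("c1", "c2"), c("G1", "G1"),
                   alignment_length = 100, s_start = 1, s_end = 100,
                   bit_score = c(180, 120))
  fwd$library_id <- "L1"
  rev <- make_hits(c("G1", "G1"), c("c1", "c2"),
                   alignment_length = 100, s_start = 1, s_end = 600,
                   bit_score = c(180, 120))
  seeds <- select_seeds(fwd, rev, ref_len1, ctg_len2)
  expect_equal(nrow(seeds), 1L)
  expect_equal(seeds$contig_id, "c1")
  expect_true(seeds$reciprocal)
  expect_equal(seeds$bit_score, 180)
})

test_that("non-reciprocal best hits are excluded from the seed set", {
  # G1's best contig is c1, but c1's best gene is G2
  ref_len <- c(G1 = 100, G2 = 100)
  fwd <- make_hits(c("c1", "c1"), c("G1", "G2"),
                   alignment_length = 100, s_start = 1, s_end = 100,
                   bit_score = c(180, 150))
  fwd$library_id <- "L1"
  rev <- make_hits(c("G1", "G2"), c("c1", "c1"),
                   alignment_length = 100, s_start = 1, s_end = 600,
                   bit_score = c(150, 180))
  out <- select_seeds(fwd, rev, ref_len, c(c1 = 600))
  expect_false(out$reciprocal[out$reference_gene_id == "G1"])
  expect_true(out$reciprocal[out$reference_gene_id == "G2"])
})

test_that("empty forward table yields an empty seed set with a warning", {
  fwd <- dplyr::mutate(make_hits(character(0), character(0)),
                       library_id = character(0))
  expect_warning(out <- select_seeds(fwd, make_hits(character(0),
                                                    character(0)),
                                     ref_len1, ctg_len2),
                 "empty")
  expect_equal(nrow(out), 0L)
})

test_that("seed selection equals exhaustive RBH enumeration", {
  set.seed(101)
  for (i in 1:30) {
    tabs <- random_rbh_tables(sample(2:6, 1), sample(2:8, 1))
    got <- select_seeds(tabs$forward, tabs$reverse, tabs$ref_len,
                        tabs$ctg_len)
    got <- got[got$reciprocal, ]
    want <- rbh_oracle(tabs$forward, tabs$reverse, tabs$ref_len,
                       tabs$ctg_len)
    expect_equal(nrow(got), length(want), info = paste("table", i))
    expect_equal(setNames(got$contig_id, got$reference_gene_id),
                 want[order(names(want))], info = paste("table", i))
  }
})

test_that("paralog extension is the union of hit subjects plus seeds", {
  contigs <- tibble::tibble(
    contig_id = c("L1_c1", "L2_c7", "L3_c9"),
    library_id = c("L1", "L2", "L3"),
    sequence = "ACGT", length = 4L
  )
  seeds <- tibble::tibble(library_id = "L1", contig_id = "L1_c1")
  hits <- make_hits(c("L1_c1", "L1_c1", "L1_c1"),
                    c("L2_c7", "L3_c9", "L2_c7"))
  cand <- extend_paralogs(seeds, hits, contigs)
  expect_equal(sort(cand$contig_id), c("L1_c1", "L2_c7", "L3_c9"))
  # duplicate rows do not double-count; no hits degenerates to the seeds
  expect_equal(nrow(cand), 3L)
  none <- extend_paralogs(seeds, make_hits(character(0), character(0)),
                          contigs)
  expect_equal(none$contig_id, "L1_c1")
})

test_that("concentrate clusters within tolerance and applies support rule", {
  set.seed(61)
  base <- random_dna_str(400)
  far <- random_dna_str(400)
  mut <- function(s, i, ch) {
    substr(s, i, i) <- ch
    s
  }
  flip <- function(ch) setdiff(c("A", "C", "G", "T"), ch)[1]
  b3 <- base
  for (p in c(10, 20, 30)) b3 <- mut(b3, p, flip(substr(b3, p, p)))
  # preconditions: the 1-sub copy is within tolerance, the 3-sub copy and
  # the unrelated sequence are beyond it
  one <- mut(base, 5, flip(substr(base, 5, 5)))
  expect_equal(bounded_edit_distance(base, one), 1L)
  expect_true(is.na(bounded_edit_distance(base, b3)))
  expect_true(is.na(bounded_edit_distance(base, far)))
  cand <- tibble::tibble(
    contig_id = c("L1_a", "L2_a", "L3_a", "L1_b", "L2_x"),
    library_id = c("L1", "L2", "L3", "L1", "L2"),
    sequence = c(base, base, one, b3, far),
    length = 400L
  )
  cl <- concentrate(cand)
  expect_equal(nrow(cl), 3L)
  a <- cl[vapply(cl$members, function(m) "L1_a" %in% m$contig_id,
                 logical(1)), ]
  expect_equal(a$library_support, 3L)
  expect_true(a$retained)
  # the 3-substitution variant and the unrelated contig are singletons
  expect_equal(sum(!cl$retained), 2L)
})

test_that("single linkage closes a non-transitive tolerance chain", {
  a <- strrep("ACGT", 100)
  sub_at <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- "T"
    s
  }
  b <- sub_at(a, c(3, 11))        # d(a,b) = 2
  c_ <- sub_at(a, c(3, 11, 19, 27)) # d(b,c) = 2, d(a,c) = 4
  expect_equal(bounded_edit_distance(b, c_), 2L)
  expect_true(is.na(bounded_edit_distance(a, c_)))
  cand <- tibble::tibble(
    contig_id = c("L1_p", "L2_q", "L3_r"),
    library_id = c("L1", "L2", "L3"),
    sequence = c(a, b, c_), length = 400L
  )
  cl <- concentrate(cand)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 3L)
  expect_equal(cl$library_support, 3L)
})

test_that("representative is the longest member with lexicographic ties", {
  base <- strrep("ACGT", 100)
  cand <- tibble::tibble(
    contig_id = c("L2_z", "L1_a", "L3_m"),
    library_id = c("L2", "L1", "L3"),
    sequence = c(base, base, paste0(base, "AC")),
    length = c(400L, 400L, 402L)
  )
  cl <- concentrate(cand)
  expect_equal(cl$representative_contig, "L3_m")
  # drop the long one: tie on length breaks to smallest (library, contig)
  cl2 <- concentrate(cand[1:2, ])
  expect_equal(cl2$representative_contig, "L1_a")
})

test_that("singleton rescue readds only seeds outside retained clusters", {
  clusters <- tibble::tibble(
    cluster_id = c("CL00001", "CL00002"),
    members = list(
      tibble::tibble(library_id = c("L1", "L2"),
                     contig_id = c("L1_a", "L2_a")),
      tibble::tibble(library_id = "L1", contig_id = "L1_solo")
    ),
    representative_library = c("L1", "L1"),
    representative_contig = c("L1_a", "L1_solo"),
    n_members = c(2L, 1L), library_support = c(2L, 1L),
    retained = c(TRUE, FALSE)
  )
  seeds <- tibble::tibble(library_id = c("L1", "L1"),
                          contig_id = c("L1_a", "L1_solo"))
  resc <- rescue_singletons(seeds, clusters)
  expect_equal(resc$contig_id, "L1_solo")
  # a non-seed singleton is not rescued
  resc2 <- rescue_singletons(seeds[1, ], clusters)
  expect_equal(nrow(resc2), 0L)
})

test_that("taxonomy filter partitions input under both policies", {
  tax <- tibble::tibble(subject_id = c("e1", "b1"),
                        superkingdom = c("Eukaryota", "Bacteria"))
  hits <- make_hits(c("c_euk", "c_bac"), c("e1", "b1"),
                    bit_score = c(200, 200))
  ids <- c("c_euk", "c_bac", "c_nohit")
  m3 <- taxonomy_filter(ids, hits, tax, "module3")
  expect_setequal(m3$kept, c("c_euk", "c_nohit"))
  expect_equal(m3$discarded, "c_bac")
  strict <- taxonomy_filter(ids, hits, tax, "strict_eukaryote")
  expect_equal(strict$kept, "c_euk")
  expect_setequal(strict$discarded, c("c_bac", "c_nohit"))
  # partition invariant
  for (r in list(m3, strict)) {
    expect_setequal(c(r$kept, r$discarded), ids)
    expect_length(intersect(r$kept, r$discarded), 0L)
  }
})

test_that("taxonomy best-hit ties break by e-value then subject id", {
  tax <- tibble::tibble(subject_id = c("a_euk", "z_bac"),
                        superkingdom = c("Eukaryota", "Bacteria"))
  # equal bit scores, bacteria has the lower e-value: bacteria wins
  hits <- make_hits(c("c1", "c1"), c("a_euk", "z_bac"),
                    bit_score = 200, evalue = c(1e-50, 1e-60))
  for (ord in list(1:2, 2:1)) {
    r <- taxonomy_filter("c1", hits[ord, ], tax, "module3")
    expect_equal(r$discarded, "c1")
  }
  # equal everything: lexicographically smallest subject id wins
  hits2 <- make_hits(c("c1", "c1"), c("a_euk", "z_bac"),
                     bit_score = 200, evalue = 1e-50)
  for (ord in list(1:2, 2:1)) {
    r <- taxonomy_filter("c1", hits2[ord, ], tax, "module3")
    expect_equal(r$kept, "c1")
  }
})

test_that("unknown taxonomy subjects are unclassified with one warning", {
  tax <- tibble::tibble(subject_id = "e1", superkingdom = "Eukaryota")
  hits <- make_hits("c1", "mystery")
  expect_warning(r <- taxonomy_filter("c1", hits, tax, "module3"),
                 "missing")
  expect_equal(r$kept, "c1")
  expect_warning(r2 <- taxonomy_filter("c1", hits, tax, "strict_eukaryote"),
                 "missing")
  expect_equal(r2$discarded, "c1")
})

test_that("merging sets collapses only exact full-length containments", {
  semi <- tibble::tibble(contig_id = c("sm1", "sm2"),
                         sequence = c(strrep("A", 100), strrep("C", 100)),
                         length = c(100L, 100L))
  auto <- tibble::tibble(contig_id = c("au1", "au2"),
                         sequence = c(strrep("A", 120), strrep("G", 80)),
                         length = c(120L, 80L))
  cross <- make_hits(c("sm1", "sm2"), c("au1", "au2"),
                     percent_identity = c(100, 95),
                     q_start = c(1, 1), q_end = c(100, 80),
                     s_start = c(1, 1), s_end = c(100, 80))
  merged <- merge_sets(semi, auto, cross)
  # sm1 is contained at 100% in au1 -> collapsed; sm2 at 95% -> kept
  expect_equal(nrow(merged), 3L)
  expect_equal(merged$provenance[merged$contig_id == "au1"], "both")
  expect_true("sm2" %in% merged$contig_id)
  # conservation: |A| + |B| - collapsed
  expect_equal(nrow(merged), 2 + 2 - 1)

  # disjoint sets: plain union
  none <- merge_sets(semi, auto, make_hits(character(0), character(0)))
  expect_equal(nrow(none), 4L)
  expect_setequal(none$provenance, c("semi_manual", "automatic"))
})

test_that("isoform edges require strict identity and length thresholds", {
  contigs <- tibble::tibble(contig_id = c("t1", "t2", "t3"),
                            length = c(500L, 450L, 400L))
  # qualifying edge t1-t2; boundary rows t1-t3 do not qualify
  hits <- make_hits(
    c("t1", "t1", "t1"), c("t2", "t3", "t3"),
    percent_identity = c(95, 90.0, 99),
    alignment_length = c(200L, 200L, 150L)
  )
  iso <- detect_isoforms(contigs, hits)
  expect_equal(sort(unique(iso$contig_id)), c("t1", "t2"))
  expect_equal(unique(iso$representative), "t1")
  # self-pairs never create edges
  self_only <- make_hits("t1", "t1", percent_identity = 100,
                         alignment_length = 500L)
  expect_equal(nrow(detect_isoforms(contigs, self_only)), 0L)
})

test_that("identical inputs give identical integration output", {
  m <- generate_libraries(n_genes = 6, n_libraries = 3,
                          n_seed_singletons = 1, n_contaminants = 1,
                          n_isoform_pairs = 1, seed = 33)
  r1 <- integrate_fixture(m)
  r2 <- integrate_fixture(m)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$integrated, r2$integrated)
  expect_identical(r1$clusters, r2$clusters)
})
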