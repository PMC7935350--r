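test_that("fixture generation is deterministic and internally consistent", {
  m1 <- generate_libraries(n_genes = 5, n_libraries = 3,
                           n_seed_singletons = 1, n_contaminants = 2,
                           n_isoform_pairs = 1, seed = 7)
  m2 <- generate_libraries(n_genes = 5, n_libraries = 3,
                           n_seed_singletons = 1, n_contaminants = 2,
                           n_isoform_pairs = 1, seed = 7)
  expect_identical(m1$contigs, m2$contigs)
  expect_identical(m1$truth, m2$truth)

  # every contig appears exactly once
  expect_false(anyDuplicated(m1$contigs$contig_id) > 0)
  # per-copy edits never exceed the configured tolerance
  expect_true(all(m1$contigs$n_edits <= 2))
  # copies stay within tolerance of their entity's exact copy
  for (e in unique(m1$contigs$entity_id)) {
    cp <- m1$contigs[m1$contigs$entity_id == e, ]
    exact <- cp$sequence[cp$n_edits == 0][1]
    d <- bounded_edit_distance(exact, cp$sequence, k = 2)
    expect_true(all(!is.na(d)))
  }
  # distinct entities are far apart (well beyond the tolerance)
  bases <- vapply(m1$entities, function(e) e$base, character(1))
  for (i in seq_along(bases)) {
    for (j in seq_len(i - 1)) {
      expect_gt(abs(nchar(bases[i]) - nchar(bases[j])), 10)
    }
  }
})

test_that("gene CDS bases are internal-stop-free on frame +1", {
  m <- generate_libraries(n_genes = 4, n_libraries = 2,
                          n_seed_singletons = 1, n_contaminants = 0,
                          n_isoform_pairs = 0, seed = 11)
  for (e in m$entities) {
    if (!e$type %in% c("gene", "singleton")) next
    orf <- longest_orf(e$base)
    expect_equal(nchar(orf$protein), nchar(e$base) / 3)
  }
  expect_equal(m$reference$aa_length,
               nchar(m$reference$protein))
})

test_that("empty fixture is valid", {
  m <- generate_libraries(n_genes = 0, n_libraries = 0,
                          n_seed_singletons = 0, n_contaminants = 0,
                          n_isoform_pairs = 0, seed = 1)
  expect_equal(nrow(m$contigs), 0L)
  expect_equal(length(m$truth$integrated_ids), 0L)
})

test_that("hit tables are emitted with by-construction identities", {
  m <- generate_libraries(n_genes = 3, n_libraries = 3,
                          n_seed_singletons = 1, n_contaminants = 1,
                          n_isoform_pairs = 1, seed = 13)
  tabs <- generate_hit_tables(m)
  # exact copies report 100% identity over the full protein
  exact <- m$contigs[m$contigs$entity_type == "gene" &
                       m$contigs$n_edits == 0, ][1, ]
  row <- tabs$forward[tabs$forward$query_id == exact$contig_id, ]
  expect_equal(row$percent_identity, 100)
  expect_equal(row$q_start, 1L)
  expect_equal(row$q_end, exact$length)
  # a 2-edit copy reports the analytic identity (aa space)
  edited <- m$contigs[m$contigs$n_edits == 2 &
                        m$contigs$entity_type == "gene", ]
  if (nrow(edited)) {
    la <- m$reference$aa_length[m$reference$entity_id ==
                                  edited$entity_id[1]]
    row2 <- tabs$forward[tabs$forward$query_id == edited$contig_id[1], ]
    expect_equal(row2$percent_identity, round(100 * (la - 2) / la, 2))
  }
  # planted isoform pairs appear in the self table with the 200 bp window
  iso_rows <- tabs$self[tabs$self$query_id != tabs$self$subject_id, ]
  expect_true(all(iso_rows$alignment_length == 200L))
  expect_true(all(iso_rows$percent_identity > 90))
  # every contig has a eukaryote or contaminant taxonomy hit
  expect_setequal(unique(tabs$nr$query_id), m$contigs$contig_id)
})

test_that("fixtures round-trip through their on-disk formats", {
  m <- generate_libraries(n_genes = 3, n_libraries = 2,
                          n_seed_singletons = 1, n_contaminants = 1,
                          n_isoform_pairs = 0, seed = 17)
  dir <- withr::local_tempdir()
  paths <- write_fixture(m, dir)
  lib <- m$libraries[1]
  got <- read_contigs(paths[[paste0("fasta_", lib)]], lib)
  want <- m$contigs[m$contigs$library_id == lib, ]
  expect_setequal(got$contig_id, want$contig_id)
  expect_equal(got$sequence[order(got$contig_id)],
               want$sequence[order(want$contig_id)])

  tabs <- generate_hit_tables(m)
  back <- read_hit_table(paths$hits_extend)
  expect_equal(nrow(back), nrow(tabs$extend))
  expect_equal(back$bit_score, tabs$extend$bit_score)

  tax <- read_taxonomy_map(paths$taxonomy)
  expect_setequal(tax$subject_id, m$taxonomy$subject_id)
  expect_true(file.exists(paths$manifest))
})

test_that("integration on a written fixture equals in-memory integration", {
  m <- generate_libraries(n_genes = 4, n_libraries = 3,
                          n_seed_singletons = 1, n_contaminants = 1,
                          n_isoform_pairs = 1, seed = 19)
  dir <- withr::local_tempdir()
  paths <- write_fixture(m, dir)
  contigs <- dplyr::bind_rows(lapply(m$libraries, function(lib) {
    read_contigs(paths[[paste0("fasta_", lib)]], lib)
  }))
  ref <- Biostrings::readBStringSet(paths$reference)
  ref_len <- setNames(Biostrings::width(ref), names(ref))
  fwd <- read_hit_table(paths$hits_forward)
  lib_of <- setNames(contigs$library_id, contigs$contig_id)
  fwd$library_id <- unname(lib_of[fwd$query_id])
  res <- integrate_all(
    contigs = contigs, reference_lengths = ref_len,
    forward_hits = fwd,
    reverse_hits = read_hit_table(paths$hits_reverse),
    extend_hits = read_hit_table(paths$hits_extend),
    nr_hits = read_hit_table(paths$hits_nr),
    taxonomy_map = read_taxonomy_map(paths$taxonomy),
    self_hits = read_hit_table(paths$hits_self)
  )
  res_mem <- integrate_fixture(m)
  expect_equal(sort(res$integrated$contig_id),
               sort(res_mem$integrated$contig_id))
  expect_equal(res$report$count, res_mem$report$count)
})
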