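NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                           names(Biostrings::GENETIC_CODE)[
                             Biostrings::GENETIC_CODE == "*"])

resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

random_cds <- function(n_codon) {
  paste(resample(NON_STOP_CODONS, n_codon, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(resample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Apply `n` random unit edits (substitution, insertion, deletion) to a
# sequence; the result is within edit distance n of the input.
apply_edits <- function(seq, n) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(n)) {
    op <- resample(c("sub", "ins", "del"), 1)
    pos <- sample.int(length(s), 1)
    if (op == "sub") {
      s[pos] <- resample(setdiff(c("A", "C", "G", "T"), s[pos]), 1)
    } else if (op == "ins") {
      s <- append(s, resample(c("A", "C", "G", "T"), 1), after = pos)
    } else if (length(s) > 1L) {
      s <- s[-pos]
    }
  }
  paste(s, collapse = "")
}

#' Generate synthetic per-library assemblies with a ground-truth manifest
#'
#' Emulates, at toy scale, the inputs of a multi-library de novo
#' transcriptome integration: gene families copied into several libraries
#' with at most `copy_divergence_bp` of accumulated mismatches/indels per
#' copy, seed singletons present in exactly one library, contaminant
#' sequences carrying non-eukaryote taxonomy labels, and optional planted
#' isoform variants sharing a 240 bp block with their parent gene. Every
#' entity draws its base length from a grid spaced 12 bp apart
#' (300-1500 bp, multiples of 3, internal-stop-free on frame +1), so
#' distinct entities are always more than 10 edits apart and redundancy
#' clusters can never merge across entities. One copy of every entity is
#' exact; the others carry 0-`copy_divergence_bp` random edits, so all
#' copies sit within the clustering tolerance of the exact copy.
#'
#' @param n_genes Genes copied into >= 2 libraries each.
#' @param n_libraries Number of libraries (>= 2 unless everything is 0).
#' @param copy_divergence_bp Maximum edits per non-exact copy (<= 2 keeps
#'   copies inside the default clustering tolerance).
#' @param n_seed_singletons Genes placed in exactly one library (become
#'   rescue truths).
#' @param n_contaminants Non-eukaryote sequences placed in two libraries
#'   (become discard truths).
#' @param n_isoform_pairs Planted isoform variants of the first genes.
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @return A `fixture_manifest` list: `params`, `contigs` (tibble with
#'   sequences, entity and edit bookkeeping), `reference` (proteins),
#'   `taxonomy`, `pedigree` (configuration consumed by
#'   [generate_pedigree_vcf()]), and `truth` (expected representatives,
#'   rescues, discards, integrated ids, isoform groups).
#' @export
generate_libraries <- function(n_genes = 10, n_libraries = 4,
                               copy_divergence_bp = 2,
                               n_seed_singletons = 2, n_contaminants = 2,
                               n_isoform_pairs = 1, seed = 1) {
  stopifnot(n_genes >= 0, n_libraries >= 0, copy_divergence_bp >= 0,
            n_seed_singletons >= 0, n_contaminants >= 0,
            n_isoform_pairs >= 0, n_isoform_pairs <= n_genes)
  n_entities <- n_genes + n_seed_singletons + n_contaminants +
    n_isoform_pairs
  if (n_entities > 0 && n_libraries < 2) {
    abort("need at least 2 libraries to place multi-library entities")
  }
  grid <- seq(300L, 1500L, by = 12L)
  if (n_entities > length(grid)) {
    abort(paste0("too many entities (", n_entities, ") to keep pairwise ",
                 "separation on the length grid (max ", length(grid), ")"))
  }
  set.seed(seed)
  libs <- sprintf("L%02d", seq_len(n_libraries))
  lens <- if (n_entities) resample(grid, n_entities) else integer(0)

  entities <- list()
  k <- 0L
  add_entity <- function(id, type, base, copies_libs, n_edits, parent = NA) {
    copies <- lapply(seq_along(copies_libs), function(j) {
      sq <- if (n_edits[j] == 0L) base else apply_edits(base, n_edits[j])
      list(library_id = copies_libs[j],
           contig_id = paste0(copies_libs[j], "_", id),
           sequence = sq, n_edits = n_edits[j])
    })
    list(entity_id = id, type = type, base = base, parent = parent,
         copies = copies)
  }

  for (g in seq_len(n_genes)) {
    k <- k + 1L
    nlib <- if (n_libraries == 2L) 2L else resample(2:min(n_libraries, 4L), 1)
    chosen <- resample(libs, nlib)
    entities[[k]] <- add_entity(sprintf("g%03d", g), "gene",
                                random_cds(lens[k] %/% 3L), chosen,
                                c(0L, resample(0:copy_divergence_bp,
                                               nlib - 1L, replace = TRUE)))
  }
  for (s in seq_len(n_seed_singletons)) {
    k <- k + 1L
    entities[[k]] <- add_entity(sprintf("s%03d", s), "singleton",
                                random_cds(lens[k] %/% 3L),
                                resample(libs, 1), 0L)
  }
  for (x in seq_len(n_contaminants)) {
    k <- k + 1L
    entities[[k]] <- add_entity(sprintf("x%03d", x), "contaminant",
                                random_dna(lens[k]), resample(libs, 2),
                                c(0L, resample(0:copy_divergence_bp, 1)))
  }
  iso_window <- 240L
  for (i in seq_len(n_isoform_pairs)) {
    k <- k + 1L
    parent <- entities[[i]]
    pre <- (lens[k] - iso_window) %/% 2L
    post <- lens[k] - iso_window - pre
    base <- paste0(if (pre) random_dna(pre) else "",
                   substr(parent$base, 1L, iso_window),
                   if (post) random_dna(post) else "")
    ent <- add_entity(sprintf("i%03d", i), "isoform", base,
                      resample(libs, 2),
                      c(0L, resample(0:copy_divergence_bp, 1)),
                      parent = parent$entity_id)
    ent$iso_prefix <- pre
    entities[[k]] <- ent
  }

  contigs <- bind_rows(lapply(entities, function(e) {
    bind_rows(lapply(e$copies, function(cp) {
      tibble(contig_id = cp$contig_id, library_id = cp$library_id,
             entity_id = e$entity_id, entity_type = e$type,
             parent = e$parent, n_edits = cp$n_edits,
             sequence = cp$sequence, length = nchar(cp$sequence),
             base_length = nchar(e$base))
    }))
  }))
  if (nrow(contigs) == 0L) {
    contigs <- tibble(contig_id = character(), library_id = character(),
                      entity_id = character(), entity_type = character(),
                      parent = character(), n_edits = integer(),
                      sequence = character(), length = integer(),
                      base_length = integer())
  }

  reference <- bind_rows(lapply(entities, function(e) {
    if (!e$type %in% c("gene", "singleton")) return(NULL)
    prot <- paste(translate_codons(
      substring(e$base, seq(1, nchar(e$base) - 2, by = 3),
                seq(3, nchar(e$base), by = 3))), collapse = "")
    tibble(entity_id = e$entity_id,
           protein_id = paste0("REF_", e$entity_id),
           protein = prot, aa_length = nchar(prot))
  }))
  if (is.null(reference) || nrow(reference) == 0L) {
    reference <- tibble(entity_id = character(), protein_id = character(),
                        protein = character(), aa_length = integer())
  }

  taxonomy <- contigs %>%
    distinct(.data$entity_id, .data$entity_type) %>%
    mutate(
      subject_id = paste0("NR_", .data$entity_id),
      superkingdom = ifelse(.data$entity_type == "contaminant",
                            resample(c("Bacteria", "Archaea", "Viruses"),
                                     dplyr::n(), replace = TRUE),
                            "Eukaryota")
    ) %>%
    select("subject_id", "superkingdom", "entity_id")

  # expected cluster representative per entity: longest copy, ties by
  # (library_id, contig_id)
  rep_of <- contigs %>%
    group_by(.data$entity_id) %>%
    arrange(desc(.data$length), .data$library_id, .data$contig_id,
            .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select("entity_id", "library_id", "contig_id")
  type_of <- setNames(contigs$entity_type[!duplicated(contigs$entity_id)],
                      contigs$entity_id[!duplicated(contigs$entity_id)])
  rep_gene <- rep_of[type_of[rep_of$entity_id] == "gene", ]
  rep_iso <- rep_of[type_of[rep_of$entity_id] == "isoform", ]
  rep_cont <- rep_of[type_of[rep_of$entity_id] == "contaminant", ]
  rescues <- contigs[contigs$entity_type == "singleton",
                     c("library_id", "contig_id")]
  discards <- if (n_genes > 0) sort(rep_cont$contig_id) else character(0)
  iso_groups <- lapply(seq_len(n_isoform_pairs), function(i) {
    ent <- sprintf("i%03d", i)
    parent <- contigs$parent[match(ent, contigs$entity_id)]
    sort(c(rep_of$contig_id[rep_of$entity_id == parent],
           rep_of$contig_id[rep_of$entity_id == ent]))
  })
  truth <- list(
    representatives = bind_rows(rep_gene, rep_iso) %>%
      arrange(.data$contig_id),
    # representatives of every retained cluster, before the taxonomy
    # filter removes the contaminants
    cluster_representatives = sort(c(
      rep_gene$contig_id, rep_iso$contig_id,
      if (n_genes > 0) rep_cont$contig_id else character(0)
    )),
    rescues = arrange(rescues, .data$contig_id),
    discards = discards,
    integrated_ids = sort(c(rep_gene$contig_id, rep_iso$contig_id,
                            rescues$contig_id)),
    isoform_groups = iso_groups
  )

  pedigree <- list(
    accessions = c("S1s", "S2s", "S3s", "S4s", "S5s", "S6s"),
    patterns = list(
      lineA = list(include = c("S5s", "S6s")),
      lineB = list(include = "S1s"),
      lineC = list(include = c("S2s", "S3s", "S4s"))
    ),
    n_specific_per_line = 3L, n_fail_qual = 2L, n_fail_dp = 2L,
    n_shared = 2L
  )

  structure(list(
    params = list(n_genes = n_genes, n_libraries = n_libraries,
                  copy_divergence_bp = copy_divergence_bp,
                  n_seed_singletons = n_seed_singletons,
                  n_contaminants = n_contaminants,
                  n_isoform_pairs = n_isoform_pairs, seed = seed,
                  iso_window = iso_window),
    libraries = libs, contigs = contigs, reference = reference,
    taxonomy = taxonomy, pedigree = pedigree, truth = truth,
    entities = entities
  ), class = "fixture_manifest")
}

surrogate_evalue <- function(matches) 10^(-pmin(matches, 300) / 10)

#' Generate every hit table the pipeline consumes, by construction
#'
#' Emits the tabular hit rows that a similarity search would report for
#' the planted homologies of a fixture manifest, with exact identities and
#' coordinates derived from the known edit counts. Bit scores use the
#' analytic surrogate `2 * matches` and e-values `10^(-matches / 10)`
#' (capped); nothing downstream depends on their absolute scale, only on
#' their ordering.
#'
#' @param manifest A [generate_libraries()] manifest.
#' @return A named list of hit tibbles: `forward` (translated contig vs
#'   reference protein, with `library_id`), `reverse` (protein vs contig),
#'   `extend` (seed vs all-library contigs), `nr` (contig vs taxonomy
#'   database), `self` (integrated-set self-search).
#' @export
generate_hit_tables <- function(manifest) {
  stopifnot(inherits(manifest, "fixture_manifest"))
  ctg <- manifest$contigs
  ref <- manifest$reference
  iso_w <- manifest$params$iso_window

  fwd <- rev_ <- ext <- nr <- self <- list()
  add <- function(lst, q, s, pid, len, mm, go, qs, qe, ss, se, ev, bs) {
    lst[[length(lst) + 1L]] <- tibble(
      query_id = q, subject_id = s, percent_identity = pid,
      alignment_length = as.integer(len), mismatches = as.integer(mm),
      gap_opens = as.integer(go), q_start = as.integer(qs),
      q_end = as.integer(qe), s_start = as.integer(ss),
      s_end = as.integer(se), evalue = ev, bit_score = bs, s_strand = "+"
    )
    lst
  }

  set.seed(manifest$params$seed + 500L)
  seedable <- ctg[ctg$entity_type %in% c("gene", "singleton"), ]
  for (i in seq_len(nrow(seedable))) {
    row <- seedable[i, ]
    la <- ref$aa_length[ref$entity_id == row$entity_id]
    m_aa <- la - row$n_edits
    pid <- round(100 * m_aa / la, 2)
    fwd <- add(fwd, row$contig_id, paste0("REF_", row$entity_id), pid, la,
               row$n_edits, 0L, 1L, row$length, 1L, la,
               surrogate_evalue(m_aa), 2 * m_aa)
    rev_ <- add(rev_, paste0("REF_", row$entity_id), row$contig_id, pid, la,
                row$n_edits, 0L, 1L, la, 1L, row$length,
                surrogate_evalue(m_aa), 2 * m_aa)
  }

  for (e in manifest$entities) {
    copies <- ctg[ctg$entity_id == e$entity_id, ]
    if (e$type %in% c("gene", "singleton")) {
      seed_copy <- copies[1L, ]
      for (j in seq_len(nrow(copies))) {
        cp <- copies[j, ]
        m <- cp$base_length - cp$n_edits
        ext <- add(ext, seed_copy$contig_id, cp$contig_id,
                   round(100 * m / cp$base_length, 2),
                   cp$base_length, cp$n_edits, 0L, 1L, seed_copy$length,
                   1L, cp$length, surrogate_evalue(m), 2 * m)
      }
    } else if (e$type == "isoform") {
      parent_copies <- ctg[ctg$entity_id == e$parent, ]
      pre <- e$iso_prefix
      for (j in seq_len(nrow(copies))) {
        cp <- copies[j, ]
        ext <- add(ext, parent_copies$contig_id[1L], cp$contig_id, 99.0,
                   200L, 2L, 0L, 1L, 200L, pre + 1L, pre + 200L,
                   surrogate_evalue(198), 396)
        for (pj in seq_len(nrow(parent_copies))) {
          self <- add(self, parent_copies$contig_id[pj], cp$contig_id,
                      99.0, 200L, 2L, 0L, 1L, 200L, pre + 1L, pre + 200L,
                      surrogate_evalue(198), 396)
        }
      }
    } else if (e$type == "contaminant") {
      gene_ids <- unique(ctg$entity_id[ctg$entity_type == "gene"])
      if (length(gene_ids)) {
        host <- ctg[ctg$entity_id == resample(gene_ids, 1), ][1L, ]
        for (j in seq_len(nrow(copies))) {
          cp <- copies[j, ]
          ext <- add(ext, host$contig_id, cp$contig_id, 75.0, 120L, 30L,
                     0L, 1L, 120L, 1L, 120L, 1e-5, 100)
        }
      }
    }
  }

  for (i in seq_len(nrow(ctg))) {
    cp <- ctg[i, ]
    m <- cp$length
    nr <- add(nr, cp$contig_id, paste0("NR_", cp$entity_id), 98.0,
              cp$length, 0L, 0L, 1L, cp$length, 1L, cp$length,
              surrogate_evalue(m), 2 * m)
    # a self search always reports the trivial self match
    self <- add(self, cp$contig_id, cp$contig_id, 100.0, cp$length, 0L, 0L,
                1L, cp$length, 1L, cp$length, surrogate_evalue(m), 2 * m)
  }

  lib_of <- setNames(ctg$library_id, ctg$contig_id)
  forward <- bind_rows(fwd)
  if (nrow(forward)) forward$library_id <- unname(lib_of[forward$query_id])
  mk <- function(lst) if (length(lst)) bind_rows(lst) else empty_hit_table()
  list(forward = if (length(fwd)) forward else
         mutate(empty_hit_table(), library_id = character(0)),
       reverse = mk(rev_), extend = mk(ext), nr = mk(nr), self = mk(self))
}

#' Generate per-accession variant call sets for a toy pedigree
#'
#' Plants, for every parental-line pattern in the manifest's pedigree,
#' `n_specific_per_line` sites whose alternate allele is present (with
#' passing QUAL/DP) in exactly that line's accessions; plus decoy sites
#' that fail the QUAL filter, fail the DP filter (including one site with
#' no DP field at all), or are shared by every accession. The returned
#' truth table is what [per_line_specific_counts()] must reproduce.
#'
#' @param manifest A [generate_libraries()] manifest.
#' @return A list: `vcf_sets` (named list of per-accession site tibbles in
#'   the [read_vcf_sites()] schema), `truth` (tibble `line`,
#'   `n_specific`), and `patterns`.
#' @export
generate_pedigree_vcf <- function(manifest) {
  stopifnot(inherits(manifest, "fixture_manifest"))
  ped <- manifest$pedigree
  set.seed(manifest$params$seed + 1000L)
  acc <- ped$accessions
  sets <- setNames(vector("list", length(acc)), acc)
  for (a in acc) {
    sets[[a]] <- tibble(contig_id = character(), pos = integer(),
                        ref = character(), alt = character(),
                        qual = numeric(), depth = integer(),
                        sample = character(), gt = character())
  }
  pos <- 0L
  plant <- function(sets, who, qual, depth, gt = "0/1") {
    pos <<- pos + 100L
    ref_alt <- resample(c("A", "C", "G", "T"), 2)
    for (i in seq_along(who)) {
      a <- who[i]
      sets[[a]] <- bind_rows(sets[[a]], tibble(
        contig_id = "vctg_1", pos = pos, ref = ref_alt[1L],
        alt = ref_alt[2L],
        qual = if (length(qual) > 1) qual[i] else qual,
        depth = if (length(depth) > 1) depth[i] else depth,
        sample = a, gt = gt
      ))
    }
    sets
  }
  ok_q <- function() round(stats::runif(1, 30, 60), 1)
  ok_d <- function() sample(5:15, 1)

  truth <- tibble(line = names(ped$patterns),
                  n_specific = ped$n_specific_per_line)
  for (nm in names(ped$patterns)) {
    inc <- ped$patterns[[nm]]$include
    for (i in seq_len(ped$n_specific_per_line)) {
      sets <- plant(sets, inc, ok_q(), ok_d())
    }
  }
  inc1 <- ped$patterns[[1L]]$include
  for (i in seq_len(ped$n_fail_qual)) {
    # QUAL exactly at / below the bound in one carrier: filtered out there
    sets <- plant(sets, inc1, c(15, rep(ok_q(), length(inc1) - 1L)),
                  ok_d())
  }
  for (i in seq_len(ped$n_fail_dp)) {
    dp <- if (i == 1L) NA_integer_ else 3L # missing DP also fails
    sets <- plant(sets, inc1, ok_q(), c(dp, rep(ok_d(),
                                                length(inc1) - 1L)))
  }
  for (i in seq_len(ped$n_shared)) {
    sets <- plant(sets, acc, ok_q(), ok_d())
  }
  list(vcf_sets = sets, truth = truth, patterns = ped$patterns)
}

#' Write a fixture to disk in its external formats
#'
#' Writes one FASTA per library, the reference protein FASTA, the five hit
#' tables, the taxonomy TSV, one VCF per pedigree accession, and the
#' manifest as JSON.
#'
#' @param manifest A [generate_libraries()] manifest.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (lib in manifest$libraries) {
    sub <- manifest$contigs[manifest$contigs$library_id == lib, ]
    p <- file.path(dir, paste0(lib, ".fasta"))
    if (nrow(sub)) write_contigs(sub, p) else writeLines(character(0), p)
    paths[[paste0("fasta_", lib)]] <- p
  }
  p <- file.path(dir, "reference_proteins.fasta")
  if (nrow(manifest$reference)) {
    Biostrings::writeXStringSet(Biostrings::BStringSet(
      setNames(manifest$reference$protein, manifest$reference$protein_id)
    ), p)
  } else {
    writeLines(character(0), p)
  }
  paths$reference <- p
  tabs <- generate_hit_tables(manifest)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0("hits_", nm, ".tsv"))
    tb <- tabs[[nm]]
    write_hit_table(tb[, c(HIT_COLS, "s_strand")], p)
    paths[[paste0("hits_", nm)]] <- p
  }
  p <- file.path(dir, "taxonomy.tsv")
  utils::write.table(manifest$taxonomy[, c("subject_id", "superkingdom")],
                     p, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  paths$taxonomy <- p
  ped <- generate_pedigree_vcf(manifest)
  for (a in names(ped$vcf_sets)) {
    p <- file.path(dir, paste0(a, ".vcf"))
    write_accession_vcf(ped$vcf_sets[[a]], a, p)
    paths[[paste0("vcf_", a)]] <- p
  }
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    params = manifest$params,
    truth = list(
      representatives = manifest$truth$representatives,
      rescues = manifest$truth$rescues,
      discards = manifest$truth$discards,
      integrated_ids = manifest$truth$integrated_ids,
      isoform_groups = manifest$truth$isoform_groups
    ),
    variant_truth = ped$truth
  ), p, auto_unbox = TRUE, digits = NA)
  paths$manifest <- p
  invisible(paths)
}

#' Write one accession's call set as a VCF 4.2 file
#'
#' @param sites Site tibble (single sample) in the [read_vcf_sites()]
#'   schema; `depth = NA` rows are written without any DP field.
#' @param sample_name Sample column name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accession_vcf <- function(sites, sample_name, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=vctg_1>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name)
  )
  body <- character(0)
  if (nrow(sites)) {
    sites <- arrange(sites, .data$contig_id, .data$pos)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s\tGT\t%s",
                    sites$contig_id, sites$pos, sites$ref, sites$alt,
                    ifelse(is.na(sites$qual), ".",
                           format(sites$qual, trim = TRUE)),
                    ifelse(is.na(sites$depth), ".",
                           paste0("DP=", sites$depth)),
                    sites$gt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Run the full integration pipeline on a fixture manifest
#'
#' Convenience wrapper: builds the hit tables from the manifest and calls
#' [integrate_all()] on them.
#'
#' @param manifest A [generate_libraries()] manifest.
#' @param ... Passed on to [integrate_all()].
#' @return The [integrate_all()] result list.
#' @export
integrate_fixture <- function(manifest, ...) {
  tabs <- generate_hit_tables(manifest)
  ref_len <- setNames(manifest$reference$aa_length,
                      manifest$reference$protein_id)
  integrate_all(
    contigs = manifest$contigs[, c("contig_id", "library_id", "sequence",
                                   "length")],
    reference_lengths = ref_len,
    forward_hits = tabs$forward, reverse_hits = tabs$reverse,
    extend_hits = tabs$extend, nr_hits = tabs$nr,
    taxonomy_map = manifest$taxonomy[, c("subject_id", "superkingdom")],
    self_hits = tabs$self, ...
  )
}
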