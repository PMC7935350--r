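#' Read assembled contigs from a FASTA file
#'
#' Reads a nucleotide FASTA of de novo assembled contigs and tags every
#' record with the library it came from. A "library" is all sequencing runs
#' of one accession or variety, assembled together.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param library_id Label of the originating library, attached to every
#'   record.
#' @return A tibble with columns `contig_id`, `library_id`, `sequence`
#'   (uppercase IUPAC), and `length` (bp).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' read_contigs(fa, "L1")
#' @export
read_contigs <- function(path, library_id) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  stopifnot(is.character(library_id), length(library_id) == 1L)
  dss <- Biostrings::readBStringSet(path)
  if (length(dss) == 0L) {
    warn(paste0("empty FASTA: ", path))
    return(tibble(
      contig_id = character(), library_id = character(),
      sequence = character(), length = integer()
    ))
  }
  ids <- sub("\\s.*$", "", names(dss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    abort(paste0("duplicate contig id(s) in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(dss))
  if (any(nchar(seqs) == 0L)) {
    abort(paste0("empty sequence for id(s): ",
                 paste(ids[nchar(seqs) == 0L], collapse = ", ")))
  }
  tibble(
    contig_id = unname(ids), library_id = library_id,
    sequence = unname(seqs), length = unname(nchar(seqs))
  )
}

#' Write contigs to FASTA
#'
#' @param contigs A contig tibble as returned by [read_contigs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contigs <- function(contigs, path) {
  stopifnot(all(c("contig_id", "sequence") %in% names(contigs)))
  dss <- Biostrings::BStringSet(setNames(contigs$sequence, contigs$contig_id))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

HIT_COLS <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
  "evalue", "bit_score"
)

#' Read a 12-column tabular local-alignment hit table
#'
#' Parses the classic 12-column tabular output of local similarity searches
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Coordinates are 1-based inclusive and kept in that
#' convention everywhere downstream. Rows whose subject interval runs
#' backwards (`s_start > s_end`, a minus-strand nucleotide hit) are flagged
#' with `s_strand == "-"` and their subject range is normalised so that
#' `s_start <= s_end`; coverage computations treat both strands identically.
#'
#' @param path Path to a tab-separated hit table (no header).
#' @return A tibble with the 12 standard columns plus `s_strand`
#'   (`"+"`/`"-"`).
#' @export
read_hit_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) {
    return(empty_hit_table())
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    abort(paste0("malformed hit table row (", nf[bad],
                 " columns, expected 12) at line ", bad, " of ", path))
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(apply(num, 1, anyNA))[1L]
    abort(paste0("non-numeric field in hit table at line ", bad, " of ", path))
  }
  hits <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = num[, 1],
    alignment_length = as.integer(num[, 2]),
    mismatches = as.integer(num[, 3]),
    gap_opens = as.integer(num[, 4]),
    q_start = as.integer(num[, 5]), q_end = as.integer(num[, 6]),
    s_start = as.integer(num[, 7]), s_end = as.integer(num[, 8]),
    evalue = num[, 9], bit_score = num[, 10]
  )
  normalize_hits(hits)
}

empty_hit_table <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    percent_identity = numeric(), alignment_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bit_score = numeric(), s_strand = character()
  )
}

#' Normalise hit-table coordinates
#'
#' Ensures `q_start <= q_end` and `s_start <= s_end`, recording the raw
#' subject orientation in `s_strand`. Idempotent: re-normalising keeps the
#' strand flag of the first pass.
#'
#' @param hits A hit tibble (with or without `s_strand`).
#' @return The hit tibble with an `s_strand` column.
#' @export
normalize_hits <- function(hits) {
  stopifnot(all(HIT_COLS %in% names(hits)))
  if (!"s_strand" %in% names(hits)) {
    hits$s_strand <- ifelse(hits$s_start > hits$s_end, "-", "+")
  }
  flip_q <- hits$q_start > hits$q_end
  if (any(flip_q)) {
    tmp <- hits$q_start[flip_q]
    hits$q_start[flip_q] <- hits$q_end[flip_q]
    hits$q_end[flip_q] <- tmp
  }
  flip_s <- hits$s_start > hits$s_end
  if (any(flip_s)) {
    tmp <- hits$s_start[flip_s]
    hits$s_start[flip_s] <- hits$s_end[flip_s]
    hits$s_end[flip_s] <- tmp
  }
  stopifnot(all(hits$alignment_length >= 1L))
  hits
}

#' Write a hit tibble back to 12-column tabular form
#'
#' Minus-strand rows are written with their subject coordinates swapped
#' back, so write + read round-trips.
#'
#' @param hits Hit tibble with `s_strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits
  minus <- out$s_strand == "-"
  tmp <- out$s_start[minus]
  out$s_start[minus] <- out$s_end[minus]
  out$s_end[minus] <- tmp
  lines <- sprintf(
    "%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.4g",
    out$query_id, out$subject_id, out$percent_identity,
    out$alignment_length, out$mismatches, out$gap_opens,
    out$q_start, out$q_end, out$s_start, out$s_end,
    out$evalue, out$bit_score
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a subject-to-superkingdom taxonomy map
#'
#' Two tab-separated columns: subject id, superkingdom. The superkingdom
#' vocabulary is closed (Eukaryota, Bacteria, Archaea, Viruses,
#' unclassified). When a subject appears more than once the last row wins
#' and a warning names the ids.
#'
#' @param path Path to the TSV.
#' @return A tibble with `subject_id` and `superkingdom`, one row per
#'   subject.
#' @export
read_taxonomy_map <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("subject_id", "superkingdom"),
                          colClasses = "character", quote = "")
  bad <- setdiff(unique(df$superkingdom), SUPERKINGDOMS)
  if (length(bad)) {
    abort(paste0("unknown superkingdom value(s): ",
                 paste(bad, collapse = ", ")))
  }
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup)) {
    warn(paste0("duplicate taxonomy rows (last wins): ",
                paste(dup, collapse = ", ")))
    df <- df[!duplicated(df$subject_id, fromLast = TRUE), , drop = FALSE]
  }
  as_tibble(df)
}

#' Read called variants from a VCF file
#'
#' Extracts one row per site and sample: position, alleles, QUAL, site
#' depth, and genotype. Site depth is INFO/DP when present, otherwise the
#' sum of per-sample FORMAT/DP; when neither exists the site carries
#' `depth = NA` and will fail any depth filter (one warning per file).
#'
#' @param path Path to a VCF 4.x file, plain or gzipped.
#' @return A tibble with columns `contig_id`, `pos`, `ref`, `alt`
#'   (comma-separated alternates), `qual`, `depth`, `sample`, `gt`.
#' @export
read_vcf_sites <- function(path) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0L) {
    return(tibble(
      contig_id = character(), pos = integer(), ref = character(),
      alt = character(), qual = numeric(), depth = integer(),
      sample = character(), gt = character()
    ))
  }
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  info_dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (anyNA(info_dp)) {
    fmt_dp <- tryCatch(
      suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(fmt_dp)) {
      dp_sum <- as.integer(rowSums(fmt_dp, na.rm = TRUE))
      dp_sum[apply(is.na(fmt_dp), 1, all)] <- NA_integer_
      info_dp[is.na(info_dp)] <- dp_sum[is.na(info_dp)]
    }
    if (anyNA(info_dp)) {
      warn(paste0("sites without any DP in ", path,
                  ": depth is missing and fails depth filters"))
    }
  }
  per_site <- tibble(
    contig_id = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, qual = qual, depth = info_dp
  )
  out <- lapply(seq_along(samples), function(j) {
    mutate(per_site, sample = samples[j], gt = unname(gt[, j]))
  })
  bind_rows(out)
}
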