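IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO <- "TGCAYRSWMKVHDBN"

revcomp <- function(x) {
  chartr(IUPAC_FROM, IUPAC_TO,
         vapply(x, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X" # any codon containing a non-ACGT symbol
  aa
}

#' Find the longest open reading frame in all six frames
#'
#' Scans the three forward and three reverse frames of a contig for the
#' longest maximal run of non-stop codons (stop-to-stop; no start codon is
#' required, because de novo contigs are frequently 5'-truncated) and
#' translates it with the standard genetic code. Codons containing any
#' non-ACGT symbol translate to `X` and never terminate a run. Ties are
#' broken by frame order +1, +2, +3, -1, -2, -3, then by smaller start
#' coordinate on the input contig.
#'
#' @param dna A single DNA string (IUPAC alphabet), length >= 3.
#' @return A list with class `orf_result`: `protein` (amino-acid string,
#'   no stop symbol), `frame` (one of 1, 2, 3, -1, -2, -3), and `nt_start`,
#'   `nt_end` (1-based inclusive coordinates on the input contig, so that
#'   `3 * nchar(protein) == nt_end - nt_start + 1`).
#' @examples
#' longest_orf("ATGAAATAA") # protein "MK", frame +1
#' @export
longest_orf <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  len <- nchar(dna)
  if (len < 3L) abort("sequence too short (need >= 3 nt)")
  strands <- list(fwd = dna, rev = revcomp(dna))

  candidates <- list()
  frame_rank <- 0L
  for (strand in c("fwd", "rev")) {
    s <- strands[[strand]]
    for (off in 0:2) {
      frame_rank <- frame_rank + 1L
      n_codon <- (len - off) %/% 3L
      if (n_codon < 1L) next
      starts <- off + 3L * (seq_len(n_codon) - 1L) + 1L
      codons <- substring(s, starts, starts + 2L)
      aa <- translate_codons(codons)
      is_stop <- aa == "*"
      run_id <- cumsum(is_stop)
      keep <- !is_stop
      if (!any(keep)) next
      for (r in split(which(keep), run_id[keep])) {
        c_start <- starts[r[1L]]            # on the scanned strand
        c_end <- starts[r[length(r)]] + 2L
        if (strand == "fwd") {
          nt <- c(c_start, c_end)
        } else {
          nt <- c(len - c_end + 1L, len - c_start + 1L)
        }
        candidates[[length(candidates) + 1L]] <- list(
          protein = paste(aa[r], collapse = ""),
          frame = if (strand == "fwd") off + 1L else -(off + 1L),
          frame_rank = frame_rank,
          nt_start = nt[1L], nt_end = nt[2L],
          n_aa = length(r)
        )
      }
    }
  }
  if (length(candidates) == 0L) {
    return(structure(list(protein = "", frame = 1L,
                          nt_start = 1L, nt_end = 0L),
                     class = "orf_result"))
  }
  key <- order(
    -vapply(candidates, `[[`, integer(1), "n_aa"),
    vapply(candidates, `[[`, integer(1), "frame_rank"),
    vapply(candidates, `[[`, integer(1), "nt_start")
  )
  best <- candidates[[key[1L]]]
  structure(best[c("protein", "frame", "nt_start", "nt_end")],
            class = "orf_result")
}

#' Bounded Levenshtein distance between two DNA strings
#'
#' Unit-cost edit distance (substitutions + insertions + deletions),
#' computed in a band of width `2k + 1` around the main diagonal, so the
#' cost is O(k * max length). Returns `NA` (the "exceeds" sentinel) as soon
#' as the distance is known to be greater than `k`; when the lengths differ
#' by more than `k` no dynamic programming is run at all. Any symbol pair
#' that is not an identical A/C/G/T match counts as a mismatch, so IUPAC
#' ambiguity codes are compared conservatively.
#'
#' The default `k = 2` is the redundancy tolerance of the cross-library
#' clustering step: two contigs are copies of the same transcript when they
#' differ by at most 2 bp of mismatches and gaps combined, measured over
#' the full sequences (global alignment). `end_free = TRUE` switches to an
#' overlap alignment in which leading/trailing gaps are free; this mode
#' serves exploration of partially overlapping contigs and is not used by
#' the default pipeline.
#'
#' @param a,b Character vectors of DNA strings (equal length, or one of
#'   them length 1; distances are computed element-wise).
#' @param k Non-negative integer tolerance.
#' @param end_free Logical; free end gaps (overlap alignment) instead of a
#'   global alignment.
#' @return An integer vector; `NA` where the distance exceeds `k`.
#' @examples
#' bounded_edit_distance("ACGT", "ACGA")        # 1
#' bounded_edit_distance("AAAA", "TTTT")        # NA (distance 4 > 2)
#' @export
bounded_edit_distance <- function(a, b, k = 2L, end_free = FALSE) {
  stopifnot(is.character(a), is.character(b), k >= 0)
  .banded_edit_distance_cpp(a, b, as.integer(k), isTRUE(end_free))
}
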