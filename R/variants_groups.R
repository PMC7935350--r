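#' Filter called variant sites on quality and depth
#'
#' Keeps sites with `qual > qual_min` and `depth > dp_min` (both strict:
#' a site at exactly QUAL 20 or DP 3 is dropped under the defaults). Sites
#' with missing depth always fail.
#'
#' @param sites Site tibble from [read_vcf_sites()].
#' @param qual_min,dp_min Strict lower bounds (defaults 20 and 3).
#' @return The filtered tibble.
#' @export
filter_variants <- function(sites, qual_min = 20, dp_min = 3) {
  keep <- !is.na(sites$qual) & sites$qual > qual_min &
    !is.na(sites$depth) & sites$depth > dp_min
  sites[keep, , drop = FALSE]
}

#' Canonical site keys
#'
#' `contig:pos:ref:alt` identifiers used to compare sites across
#' per-accession VCFs.
#'
#' @param sites Site tibble.
#' @return Character vector of keys.
#' @export
site_key <- function(sites) {
  paste(sites$contig_id, sites$pos, sites$ref, sites$alt, sep = ":")
}

gt_has_alt <- function(gt, multiallelic_as_alt = TRUE) {
  vapply(strsplit(gt, "[/|]"), function(a) {
    idx <- suppressWarnings(as.integer(a))
    idx <- idx[!is.na(idx)]
    if (multiallelic_as_alt) any(idx >= 1L) else any(idx == 1L)
  }, logical(1))
}

#' Per-accession alternate-allele presence sets
#'
#' For each accession's (filtered) site tibble, the set of site keys whose
#' genotype carries the alternate allele. A heterozygous call counts as
#' present. By default any allele index >= 1 counts as "alt" at
#' multi-allelic sites, matching the set-intersection semantics of
#' bitmask-style variant comparison tools; `multiallelic_as_alt = FALSE`
#' restricts presence to allele index 1 exactly.
#'
#' @param vcf_sets Named list (accession -> site tibble) of single-sample
#'   call sets.
#' @param multiallelic_as_alt Collapse all alternate alleles (default).
#' @return Named list of character vectors of site keys.
#' @export
presence_sets <- function(vcf_sets, multiallelic_as_alt = TRUE) {
  stopifnot(!is.null(names(vcf_sets)), all(nzchar(names(vcf_sets))))
  lapply(vcf_sets, function(s) {
    if (nrow(s) == 0L) return(character(0))
    unique(site_key(s)[gt_has_alt(s$gt, multiallelic_as_alt)])
  })
}

#' Select group-specific variant sites by presence bitmask
#'
#' A site is specific to a group when its alternate allele is present in
#' every `include` accession and absent from every excluded accession.
#' `exclude` defaults to the complement of `include` within `universe`, the
#' presence/absence-intersection reading of group specificity.
#'
#' @param presence Named list of per-accession presence sets (from
#'   [presence_sets()]).
#' @param include Character vector of accessions that must carry the
#'   allele (non-empty).
#' @param universe All accessions under consideration; defaults to
#'   `names(presence)`.
#' @param exclude Accessions that must lack the allele; default
#'   `setdiff(universe, include)`.
#' @return Sorted character vector of qualifying site keys.
#' @export
group_specific_sites <- function(presence, include,
                                 universe = names(presence),
                                 exclude = NULL) {
  stopifnot(length(include) >= 1L)
  unknown <- setdiff(c(include, exclude), universe)
  if (length(unknown)) {
    abort(paste0("accession(s) not in universe: ",
                 paste(unknown, collapse = ", ")))
  }
  if (is.null(exclude)) exclude <- setdiff(universe, include)
  if (length(intersect(include, exclude))) {
    abort("include and exclude overlap")
  }
  missing_acc <- setdiff(c(include, exclude), names(presence))
  if (length(missing_acc)) {
    abort(paste0("no presence set for accession(s): ",
                 paste(missing_acc, collapse = ", ")))
  }
  sel <- Reduce(intersect, presence[include])
  for (acc in exclude) sel <- setdiff(sel, presence[[acc]])
  sort(sel)
}

#' Count group-specific variants per parental line
#'
#' Applies the quality/depth filter to every accession's call set, builds
#' the alternate-allele presence sets, and counts the sites matching each
#' pedigree-derived group pattern.
#'
#' @param vcf_sets Named list (accession -> site tibble from
#'   [read_vcf_sites()]).
#' @param patterns Named list of patterns; each a list with `include` and
#'   optional `exclude` (see [group_specific_sites()]).
#' @param qual_min,dp_min Passed to [filter_variants()].
#' @param multiallelic_as_alt Passed to [presence_sets()].
#' @return A tibble with `line`, `n_specific`, and a `sites` list column
#'   of the qualifying site keys.
#' @export
per_line_specific_counts <- function(vcf_sets, patterns, qual_min = 20,
                                     dp_min = 3,
                                     multiallelic_as_alt = TRUE) {
  stopifnot(!is.null(names(patterns)), all(nzchar(names(patterns))))
  filtered <- lapply(vcf_sets, filter_variants, qual_min = qual_min,
                     dp_min = dp_min)
  presence <- presence_sets(filtered, multiallelic_as_alt)
  rows <- lapply(names(patterns), function(nm) {
    p <- patterns[[nm]]
    sel <- group_specific_sites(presence, include = p$include,
                                universe = names(vcf_sets),
                                exclude = p$exclude)
    tibble(line = nm, n_specific = length(sel), sites = list(sel))
  })
  bind_rows(rows)
}
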