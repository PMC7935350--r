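---
title: "Integrating multi-library de novo transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating multi-library de novo transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txintegrate)
```

## The problem

When a non-model organism has no reference genome, each RNA-Seq library
(all runs from one accession or variety, assembled together) yields its
own de novo contig set. These per-library sets are massively redundant
across libraries — the same transcript is re-assembled many times with a
handful of base differences — yet each also contains library-specific
transcripts, fragments, and contaminating sequences from microbes on the
sampled tissue. `txintegrate` implements a multi-stage procedure that
collapses K per-library assemblies into one non-redundant transcript
catalogue while keeping single-library transcripts that carry independent
evidence of being real genes, and then evaluates the result.

The pipeline was designed around a conifer (sugi, *Cryptomeria japonica*)
male-sterility breeding programme — ten libraries from male strobili,
leaf, and inner bark of related accessions — but nothing in the code is
species-specific.

## Pipeline stages

**Seed selection (module 1).** Each library's contigs are compared, in
translated (protein) space, against a curated reference protein set. Two
pre-filters act on each contig-protein pair: HSPs shorter than 20 aa are
discarded, and the surviving HSPs, merged as intervals, must cover at
least 50% of the reference protein (inclusive). Each reference gene is
then linked to exactly one contig — the highest bit score, with ties
broken by lower e-value, larger merged subject coverage, then smallest
contig id — and the link is kept only when it is a reciprocal best hit:
the reverse search must rank that gene as the contig's best partner under
the same ordering. The tie-break chain is a total order, so reruns are
byte-identical; the chain itself is this package's choice (the procedure
it implements does not specify one).

**Paralog extension and redundancy clustering (module 2).** Seeds are
used as nucleotide queries against all libraries, with no filtering — the
aim is to pull in every homolog, including paralogs that arose after the
lineage split from the reference taxa. The resulting candidates are
clustered: two contigs are "the same transcript" when their global edit
distance (substitutions + insertions + deletions, unit cost) is at most
2 bp. Clusters are connected components of this relation (single
linkage). The tolerance relation is not transitive — a chain a–b (d = 2),
b–c (d = 2) with d(a, c) = 4 forms one cluster — and the test suite pins
this behaviour down explicitly. Each cluster's representative is its
longest member (ties: smallest `(library_id, contig_id)`), and only
clusters spanning at least two libraries are retained: a transcript
assembled independently from two accessions' reads is very unlikely to be
an assembly artefact.

**Singleton rescue.** The two-library rule would silently delete genuine
genes expressed in only one library. A seed contig — one that already
carries reciprocal-best-hit protein evidence — belonging to no retained
cluster is therefore added back.

**Taxonomy filter (module 3).** Every surviving contig is classified by
the superkingdom of its best hit (bit score, then e-value, then subject
id) against a broad annotated database. The `module3` policy discards
confident non-eukaryote matches and keeps eukaryote matches, unclassified
subjects, and contigs with no hit at all; `strict_eukaryote` keeps only
confirmed eukaryote matches. Both are implemented because the source
procedure applies the filter twice with wordings that differ on no-hit
contigs; neither policy is asserted as the original's, and the choice is
a parameter.

**Merge with an automatic pipeline.** When a second, automatically
integrated set exists, the two are merged by homology. The collapse rule
here is deliberately conservative: a contig is absorbed only when a
cross-hit shows 100% identity and the merged hit intervals fully contain
the shorter sequence. Both knobs (`min_identity`, `min_containment`) are
exposed, because "merge by homology" admits many readings and the
conservative one is the only one that cannot create chimeric entries.

**Isoform grouping.** Within the integrated set, a self-search (minimum
word/seed size 100 bp) links two contigs as isoforms when some HSP
exceeds 90% identity *and* 150 bp length — both strictly. Groups are
connected components of size ≥ 2. The 90% figure is read as percent
identity of the matching HSP; a covered-fraction reading is available via
the coverage machinery but is not the default.

## Evaluation

**Mutual coverage.** For two transcript sets A and B, the HSPs of each
query-subject pair are merged on the measured sequence's axis; a
sequence's coverage is the *best single partner's* merged coverage, not
the union over partners (pooling partners would let many fragments
masquerade as one full-length match; a `union_partners` mode exists for
comparison). A sequence counts as covered only strictly above the 75%
threshold. Denominators are full set sizes, and percentages are rounded
half-up to two decimals — `percentage(45612, 56399)` prints
`r percentage(45612, 56399)`, which is how the package reproduces the
reference coverage-comparison cells shipped in
`inst/extdata/reference_coverage_counts.tsv`.

**Mapping rate.** From pre-counted totals only: `1 - unmapped / total`.
The package deliberately does not parse BAM files; any aligner's flagstat
output can be tabulated.

## Variants and pedigree groups

Called variants are filtered with strict bounds — QUAL > 20 and
depth > 3; a site at exactly QUAL 20 or DP 3 fails, as does a site with
no recoverable depth. Depth is INFO/DP where present, falling back to the
sum of per-sample FORMAT/DP (logged once per file). A variant is
*specific* to an accession group when its alternate allele is present in
every group member and absent from every other accession in the universe
— the presence/absence-bitmask semantics of set-intersection tools.
Presence is genotype-based (a heterozygous call counts), and by default
any alternate allele index counts as "present", mirroring how bitmask
intersections collapse multi-allelic sites; an allele-1-only mode is
available.

## Thresholds

| Parameter | Default | Comparison | Acts on |
|---|---|---|---|
| `min_hsp_aa` | 20 aa | ≥ (filter keeps ≥) | seed pre-filter, per HSP |
| `min_subject_coverage` | 0.5 | inclusive ≥ | merged reference-protein coverage |
| `concentrate_tolerance_bp` | 2 bp | ≤ | global edit distance between contigs |
| `min_library_support` | 2 | ≥ | distinct libraries per cluster |
| `isoform_min_identity_pct` | 90 | strict > | self-hit percent identity |
| `isoform_min_hsp_bp` | 150 bp | strict > | self-hit HSP length |
| `coverage_threshold` | 0.75 | strict > | per-sequence mutual coverage |
| `qual_min` / `dp_min` | 20 / 3 | strict > | variant QUAL / site depth |

The inclusive-versus-strict choices follow the wording of the procedure
being implemented ("minimum ratio … was 50%" versus "over 75%", "QUAL >
20") and are frozen in boundary tests.

## The synthetic-data generator

Real ten-library assemblies cannot be reproduced at desk scale, so the
package ships a generator whose outputs have *known* ground truth:

* Each entity (gene, seed singleton, contaminant, isoform variant) draws
  its base length from a grid spaced 12 bp apart (300–1500 bp, multiples
  of 3, internal-stop-free on frame +1). Since edit distance is at least
  the length difference, distinct entities are always > 10 edits apart
  and clusters can never merge across entities, whatever the random
  sequence content.
* One copy of every entity is exact; further copies carry 0–2 random
  edits. All copies are therefore within tolerance of the exact copy, so
  single-linkage clustering provably reunites them even when two edited
  copies are up to 4 edits from each other.
* Genes are copied into 2–4 random libraries; singletons into exactly
  one; contaminants into two (with Bacteria/Archaea/Viruses taxonomy
  labels and a weak planted hit to a gene seed, so they flow through the
  candidate stage and must be caught by the taxonomy filter, not merely
  never enter); isoform variants share a 240 bp block with their parent
  gene inside otherwise random flanks.
* Hit tables are emitted *by construction* from the known copy
  coordinates rather than by running an aligner: identities are analytic
  (`100 · matches / length`), bit scores use the surrogate `2 · matches`
  and e-values `10^(-matches/10)` (capped). Nothing downstream depends on
  their absolute scale, only their ordering. A real search engine's
  tables can be substituted through the same readers.
* The pedigree module plants, per parental line, sites present exactly in
  that line's accessions with passing QUAL/DP, plus decoys that fail the
  QUAL bound, fail the depth bound (one with no DP field at all), or are
  shared by all accessions.

What passing the end-to-end suite shows, and what it does not: the
pipeline provably recovers planted structure under clean separation
(entities far apart, copies within tolerance, hit tables complete). Real
data violate all three — fragmented contigs sit at intermediate
distances, searches miss true homologs, and chimeras link unrelated
genes — so fixture recovery demonstrates correctness of the logic, not
field performance of the thresholds.

## Numerical and degenerate-input choices

* The banded edit-distance kernel (C++) computes a width `2k + 1` band
  and returns the "exceeds" sentinel (`NA`) as soon as a whole band row
  exceeds `k`; a length difference > `k` short-circuits without any DP.
  IUPAC ambiguity codes are never wildcards — any non-identical pair is a
  mismatch — which is conservative and deterministic. An end-gap-free
  (overlap) mode exists for exploring partially overlapping contigs but
  the default, used by the pipeline, is the global distance: it is the
  strictest reading of a "2 bp mismatch/gap tolerance" between redundant
  copies.
* ORFs are stop-to-stop maximal runs; no start codon is required because
  de novo contigs are frequently 5'-truncated. Ties across frames break
  +1, +2, +3, −1, −2, −3, then smaller start coordinate. Codons
  containing non-ACGT symbols translate to `X` and never terminate a run.
  A sequence whose every frame is all-stops yields an empty protein.
* Interval merging coalesces adjacent intervals (`end + 1 == start`), is
  idempotent and permutation-invariant; merged coverage can therefore
  never exceed 100%. A raw-sum mode (which can) is kept for comparison
  with summation-style coverage figures.
* Hit-table normalisation maps minus-strand subject rows to ascending
  coordinates with a strand flag; coverage treats both strands
  identically, because transcript-vs-transcript searches legitimately hit
  both.
* Every grouping output (clusters, isoform groups) is ordered by a
  deterministic key and every selection uses a total order, so identical
  inputs give byte-identical outputs.

## Problem sizes

The shipped tests and the acceptance script use: 1,000 random string
pairs (length ≤ 30) against a full-matrix edit-distance oracle; 500
random HSP sets against a per-position boolean coverage oracle; 200
random small tables (≤ 6 genes × ≤ 8 contigs) against exhaustive
reciprocal-best-hit enumeration; 100 random presence matrices (≤ 5
accessions × ≤ 20 sites) against exhaustive bitmask enumeration; and 20
seeded fixtures of 5–50 genes across 3–10 libraries for end-to-end
recovery. These sizes give every code path multiple hits while keeping a
full run in the low minutes on one core.

## Known limitations

* The package consumes similarity-search output; it never runs BLAST or
  an aligner itself, so its results are only as complete as the supplied
  hit tables.
* Single-linkage clustering can, in principle, chain through a series of
  borderline pairs; with a 2 bp tolerance this is unlikely but not
  impossible on real data, and the cluster table records every member so
  such chains are auditable.
* Mapping rates are computed from pre-counted totals; SAM/BAM parsing is
  out of scope.
* The automatic (evidence-directed) assembly pipeline that produces the
  second input set of the merge stage is external; only the merge itself
  is implemented.
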