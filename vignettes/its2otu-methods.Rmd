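---
title: "Methods: two-tier OTU analysis of multicopy ITS2 amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-tier OTU analysis of multicopy ITS2 amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

*Symbiodinium* ITS2 is a multicopy tandem-array marker. Concerted evolution
homogenizes the array around one or two numerically dominant copies, but
not fast enough to remove a long tail of rare intragenomic variants, so an
amplicon library from even an isoclonal culture contains hundreds of
distinct sequences whose median mutual divergence is below ~2%. Between
clades (A–I) the same marker diverges by well over 10%, to the point that
cross-clade alignments are not meaningful. Any single flat clustering
threshold therefore fails: it either merges clades or splinters genomes.

`its2otu` implements the two-tier response to this structure:

* **Tier 1 (clades).** All unique variants are clustered by
  average-neighbour (average-linkage/UPGMA) clustering of uncorrected
  pairwise distances at `clade_cutoff` (default **0.15**). Each resulting
  cluster is a clade bin; bins are numbered by descending read count and
  labelled with the clade letter of their dominant variant's best
  reference hit.
* **Tier 2 (species/type OTUs).** Within each clade, variants shorter than
  90% of the clade's sequences are discarded, and the remainder are
  clustered at `otu_cutoff` (default **0.03**, i.e. 97% similarity). The
  fine cut-off is chosen so that all variation of isoclonal
  (single-genome) control cultures collapses into one OTU — intragenomic
  variation stays inside an OTU; anything that splits is treated as a
  distinct type.

Each OTU is represented by its most abundant member (ties broken by the
lexicographically smaller sequence, for reproducibility) and annotated by
exhaustive global alignment against a reference database of named ITS2
types; the hit with the highest percent identity wins, with ties and
identities below 90% reported as `unclassified_<clade>` rather than forced
onto a type.

## Distances

All distances are uncorrected (*p*-) distances computed on pairwise global
alignments:

* **Alignment.** Affine-gap Needleman–Wunsch; a gap of length $k$ costs
  `gap_open` $+ k\,\cdot$ `gap_extend`. Default scores are
  (+2, −2, −4, −2) for match/mismatch/gap-open/gap-extend — fixed,
  arbitrary within reason, and echoed into output metadata so runs are
  comparable. Traceback ties are broken deterministically (diagonal, then
  up, then left), so alignments are bit-stable.
* **Distance.** With the default `gapPolicy()`, each maximal internal gap
  run contributes one difference and one comparable position (an indel
  event is one event regardless of length), mismatched base columns
  contribute one difference each, and terminal gap columns are excluded.
  `gap_run_counts_as = "each"` and `ignore_terminal_gaps = FALSE` are
  available for sensitivity analysis.

Using one pairwise-alignment engine for both tiers (rather than a
multiple-sequence alignment within clades and a pairwise aligner across
them) keeps the distance well-defined for every pair and removes an MSA
dependency. This is a deliberate design decision: absolute distances can
shift slightly relative to an MSA-based computation, which is exactly why
the calibration module exists — cut-offs are re-derivable from controls
under *this* distance definition, and the bundled controls confirm that
0.03/0.15 remain the operative values.

## Average-neighbour clustering

The distance between clusters is the arithmetic mean of all cross-pair
distances; clusters merge while the smallest such mean is ≤ the cut-off
(closed threshold: a merge at exactly the cut-off happens). Because
average linkage is monotone, this greedy procedure equals cutting the full
UPGMA tree at the threshold, which is how it is implemented
(`stats::hclust(method = "average")` plus an explicit union-find cut with a
$10^{-9}$ tolerance that absorbs floating-point drift of successive
Lance–Williams updates). The test suite cross-checks this implementation
against a naive $O(n^3)$ re-agglomeration oracle on hundreds of random
matrices. Cluster numbering follows first appearance in label order;
variant labels themselves follow the canonical table order (descending
total count, then lexicographic sequence), so the whole chain is
deterministic.

# Read-level filtering

Defaults mirror standard practice for this assay and are all in
`filterPolicy()`:

| parameter | default | meaning |
|---|---|---|
| `max_barcode_mismatch` | 0 | 5'-anchored Hamming match of the sample barcode |
| `max_fwd_primer_mismatch` | 2 | forward-primer mismatches, IUPAC-aware |
| `max_ambiguous` | 0 | N bases tolerated per read |
| `max_homopolymer` | 4 | longest tolerated single-base run (a run of 5 fails) |
| `min_length` | 250 | minimum post-trim length (nt) |
| `rev_primer_error_rate` | 0.15 | mismatch rate allowed when removing the reverse primer |

Filter order is barcode → forward primer → reverse-primer trim →
ambiguity → homopolymer → length; length is assessed after all trimming.
Within the quality filter the first failing rule is the reported reason, so
per-reason tallies in the `FilterReport` are disjoint and
`kept + discarded = input` holds at every stage.

Design notes:

* Barcode and primer matching count substitutions only (no indels):
  barcodes are fixed-length, and the "more than 2 mismatches" criterion is
  a substitution count. The reverse primer is found by a sliding-window
  substitution scan (best window = lowest mismatch rate, then longest
  overlap, then leftmost), accepting full occurrences anywhere or ≥ 8 nt
  3'-overlaps of a primer prefix. Indels inside the primer match are not
  modelled; for the short primers used here the practical difference from
  an edit-distance scan is negligible, and the rate arithmetic matches the
  documented 0.15 threshold exactly.
* Reads without a reverse-primer hit are kept untrimmed by default (the
  behaviour of the standard adapter trimmer); `require_rev_primer = TRUE`
  discards them with reason `rev_primer_missing`.
* Base qualities, when present, are carried but ignored by filters: all
  criteria are sequence-based.
* Dereplication is order-independent, and singletons are defined
  dataset-wide (a sequence seen once in each of two samples is *not* a
  singleton).

## Chimera flagging

A deliberately simplified two-parent abundance-skew detector replaces the
full UCHIME algorithm: a variant is flagged when some split point yields a
5' segment within 1 mismatch of one ≥ 2-fold more abundant variant and a 3'
segment within 1 mismatch of a different one, while its best single-parent
match has ≥ 3 mismatches. Comparisons are left-/right-anchored Hamming
scans. The check is pooled across samples by default (`per_sample = TRUE`
switches to per-sample abundances, removing the union of flags). The stage
is pluggable — users can substitute external chimera calls by filtering the
variant table themselves. The detector is conservative in the direction of
over-flagging rare variants whose substitutions happen to be covered
piecewise by two abundant neighbours; at the default error rates this
affects low-count variants only and does not move OTU-level results, which
the end-to-end tests confirm.

# Length screen

"Shorter than 90% of the clade's sequences" is read as: discard a variant
iff at least 90% of the clade's variants are strictly longer. This is
realized as a nearest-rank threshold (the length at rank
$\lfloor (1-q)\,n + 10^{-9} \rfloor + 1$ of the sorted lengths, default
$q = 0.9$), discarding variants strictly shorter than it. The alternative
reading — shorter than 90% of the *modal* length — was rejected because it
is not scale-free across clades with different amplicon lengths and does
not reproduce the worked behaviour (with nine 300-nt variants and one
200-nt variant, exactly the 200-nt variant must fall).

# Calibration from isoclonal controls

`intragenomicStats()` restricts a control sample to variants with ≥ 100
reads in that sample (guarding against contamination and ultralow-abundance
copies), computes all pairwise distances, and reports
mean/median/min/max/range; the 100-read floor applies per sample, matching
the per-culture framing of control analyses, and the median of an even
number of distances is the midpoint of the central pair. Fewer than two
qualifying variants yields an explicit insufficient-variants row, never
silent zeros.

`deriveSpeciesCutoff()` clusters each control's qualifying variants at
every value of an ascending grid (default 0.01–0.10 in steps of 0.01,
which brackets the operative 0.03 cheaply) and returns the smallest grid
value at which *every* control collapses into one OTU; per-control OTU
counts are non-increasing along the grid by construction. If no grid value
works the result is reported as "none in grid"; all-degenerate controls
fall back to the smallest grid value with a warning.

`cladeCutoffCheck()` validates a candidate clade cut-off against known
clade labels via the adjusted Rand index (exact recovery = ARI of 1).

# The synthetic-data generator

The simulator emulates the features of this data type that drive the
analysis, with defaults fixed once as the study conditions:

* **Genome model**: 1–2 dominant ITS2 copies carrying `dominance` = 0.8 of
  the rDNA mass (split 2:1 when there are two), plus `n_rare_variants`
  rare variants generated by substituting a dominant copy at up to
  `max_intra_divergence` (default 0.02) of its sites, with geometrically
  decaying frequencies (`rare_decay` = 0.8). These defaults put the
  dominant copy ~20-fold above the second most common variant and the top
  five variants above 80% of reads — the long-tail structure this marker
  shows in practice.
* **Clade templates**: seeded random sequences (~330 nt, amplicon scale;
  homopolymer runs capped at 3 so templates pass the filters) with
  pairwise divergence forced above 0.20 by rejection sampling, matching
  the clade-separation premise without shipping real sequences.
* **Copy-number bias**: read-sampling weight = cell proportion ×
  `rdna_copy_weight`, so lineages with larger rDNA arrays dominate read
  counts at equal cell numbers.
* **Read model**: reads are `barcode + forward primer + mutated template +
  reverse primer`, with per-base substitutions (default 2 × 10⁻⁴), ±1
  indels inside homopolymer runs ≥ 3 (default 10⁻⁴ per run-base,
  reflecting pyrosequencing chemistry), and chimeras formed by splicing
  two distinct templates at a random interior breakpoint. The generator
  emulates *denoised* reads — flowgram-level noise removal happens
  upstream of this pipeline — hence the low residual error rates.
* **Determinism**: every generator call takes a seed and restores the RNG
  state; identical seeds give byte-identical output, and a truth table
  maps every read to its template, species, applied errors and chimera
  status.

What the simulator does **not** emulate: quality-score realism, PCR-cycle
amplification bias within a genome, flowgram-level error structure, and
the possibility that two biological species share an ITS2 sequence.
Passing tests on synthetic data therefore demonstrate that the pipeline's
logic is correct under the stated genomic model — not that 0.03 is the
biologically optimal cut-off for any particular real dataset, which is
precisely why the calibration module takes user controls.

# Numerical choices and degenerate inputs

* Merges at exactly the cut-off are performed (closed threshold); a
  $10^{-9}$ tolerance absorbs float drift in averaged heights.
* Identical sequences short-circuit to distance 0 without alignment; a
  pair with no comparable columns (terminal-gap-only overlap) is an error,
  not a zero.
* Single-variant matrices cluster trivially; empty matrices, empty
  reference databases, unknown samples, and depths exceeding the sample
  total are errors with named messages. Pipeline stages that empty the
  read set raise stage-labelled errors.
* Rarefaction uses the exact hypergeometric expectation
  $E[S_n] = \sum_i \left(1 - \binom{N-N_i}{n}\big/\binom{N}{n}\right)$ in
  log-gamma arithmetic — the exact expectation of the resampling procedure
  that rarefaction tools approximate — with a seeded Monte-Carlo
  cross-check mode.
* Representative and rank-abundance ties break on the lexicographically
  smaller sequence; count tables are written in canonical order; outputs
  carry tool version, a parameter hash and the seed, so re-runs are
  byte-identical.

# Problem sizes

The bundled tests and the acceptance script run entirely on synthetic
data at desk scale, chosen to exercise every code path comfortably within
a routine test run: isoclonal and pooled-culture simulations of 4 000 to
10 000 reads with ~30–60 retained variants, oracle comparisons on 200
random matrices of up to 12 sequences, rarefaction cross-checks at 10 000
Monte-Carlo replicates, and calibration on control sets with planted merge
heights of 0.01–0.03. On these sizes the full pipeline completes in a few
seconds on one core; cost is dominated by the all-pairs alignment, which
is $O(n^2 L^2)$ in variant count $n$ and length $L$ and is implemented in
C++.

# Known limitations

* ITS2 alone cannot delimit species: distinct lineages can share a
  sequence, and closely related named types (single-base differences)
  collapse into one OTU at 0.03 by design. OTUs here are provisional,
  deliberately deflating rather than inflating diversity.
* Read shares across lineages confound cell abundance with rDNA copy
  number and extraction/PCR efficiency; only OTU presence is
  interpretable across species.
* The chimera flagger is a simplification; for publication-grade chimera
  removal substitute a dedicated tool and filter the variant table.
* Cross-clade distances from pairwise global alignment are saturated,
  effectively non-homologous comparisons; they are used only to separate
  clades, never to interpret magnitudes above ~0.15.
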