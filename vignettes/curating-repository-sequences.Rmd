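---
title: "Curating public-repository sequences for a target locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating public-repository sequences for a target locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcurate)
```

## The problem

Public nucleotide repositories accumulate records with mistaken species
labels, backward-read submissions, stray RefSeq duplicates, uncertain
open-nomenclature names (cf./aff./sp./ssp.) and plain sequencing
artefacts. For a widely sequenced marker such as mitochondrial
cytochrome-b (Cytb, roughly 1,140 nt in vertebrates), these problems are
frequent enough to distort downstream phylogenetics, barcoding and
conservation genetics. seqcurate implements a deterministic, offline
curation pipeline for such a corpus: every decision a GUI-based workflow
would make by eye is replaced by an explicit algorithm, so a run can be
repeated byte for byte.

The pipeline stages are:

1. **records** — parse FASTA plus optional metadata, normalise organism
   names, drop RefSeq (`NC_`) duplicates, reconcile names against a
   user-supplied synonymy table, and split complete binomials from
   uncertain-taxonomy records.
2. **refmap** — orient every record against a reference locus and
   extract the locus region, recovering backward-read submissions and
   trimming mitogenome-scale records to the target interval.
3. **msa** — align conspecific sequences, resolve frame-breaking gaps
   under the vertebrate mitochondrial code, trim ambiguous row ends.
4. **divergence** — uncorrected pairwise divergences within species and
   genera.
5. **curation** — threshold-based conflict flagging and report assembly.
6. **coverage_summary** — per-position coverage, best-region search and
   database summary statistics.

## The divergence screen

The genetic distance used throughout is the uncorrected p-distance:
for two rows of one alignment, the proportion of mismatching sites among
*comparable* sites, a site being comparable when both characters are in
{A, C, G, T} (pairwise deletion of gaps, N and ambiguity codes). No
substitution-model correction is applied. A pair with fewer than
`min_overlap` (default 100) comparable sites has no defined distance:
such pairs neither accept nor flag a sequence — absence of evidence is
kept distinct from evidence either way.

Flagging applies one threshold `t`, default 3% — a conservative
community value for amphibian Cytb that should be re-estimated for other
loci and clades — with the two complementary screens:

* **Within species** (accept `<= t`, examine `> t`): sequences are
  grouped by single-linkage at `t` over defined distances. If several
  clusters result, every member outside the largest is flagged; an
  equal-size tie keeps the cluster containing the lexicographically
  smallest label. Flagging whole minority clusters isolates probable
  mislabels without condemning the majority; the tie rule is an explicit
  convention recorded on the report, since no principled rule exists for
  two equal halves.
* **Within genera** (accept `> t`, examine `<= t`): every heterospecific
  pair at or below `t` flags both members, deduplicated per sequence
  with the nearest partner kept as evidence.

Both directions of the inequalities are exact: `d == t` is accepted by
the first screen and flagged by the second.

On monotonicity in `t`: the intrageneric flag *set* can only grow as `t`
grows (containment). For the intraspecific screen, the flag *count*
`n - |largest cluster|` can only shrink, because single-linkage
components only merge; the flagged *set* however is not always nested —
the identity of the largest cluster can switch as clusters merge, which
is a property of any keep-the-majority rule, not of the implementation.
The package tests check exactly the guarantees stated here.

A sequence flagged by either screen lands in the conflict report with
its category, worst/nearest partner, distance, comparable-site count and
the threshold used. Deciding *why* a sequence conflicts
(misidentification, contamination, hybridization/introgression,
submission error) requires literature and specimen knowledge; the report
carries empty `verdict`/`rationale`/`reference` columns for that human
step and the tool never fills them. With the default `policy = "exclude"`
all flagged sequences are withheld from the curated output; `"annotate"`
keeps them.

## Reference mapping

Each record and its reverse complement are aligned against the reference
locus with an affine-gap Gotoh kernel (match +1, mismatch −1, a gap run
of length *k* costs −4 − *k*; IUPAC ambiguity codes score 0 against
anything, so legitimate ambiguity calls are never penalised). The
higher-scoring strand decides the orientation; a score tie or an
identity below 50% over comparable aligned sites routes the record to
the conflict report as a mapping failure, and an aligned span shorter
than `min_length` (default 100 nt) does the same.

Two end treatments of the same kernel are used deliberately:

* **Mapping uses local (Smith–Waterman) ends.** A free-end-gap
  ("semi-global") alignment can skip a prefix of only one of the two
  sequences, so a vector-padded fragment that belongs to an interior
  reference interval could never shed both its padding and the
  reference prefix. Local ends — what read mappers effectively use —
  skip both, and the aligned block still spans the whole locus region
  for genuine sequences.
* **The conspecific multiple alignment uses overlap (free end-gap)
  ends**, so ragged but genuine sequence ends are kept and padded
  rather than clipped.

Both modes are verified exactly against an independent implementation
(`Biostrings::pairwiseAlignment`, types `"local"` and `"overlap"`) in
the test suite.

Records longer than twice the reference (mitochondrial genomes) are
pre-screened with exact 12-mer seeding to locate the candidate window
(±200 nt margin) before dynamic programming; the tests assert the
windowed result equals full-length DP on such records. Coordinates are
0-based, half-open, on the reference forward strand.

## Per-species alignment and gap resolution

Conspecific sequences are aligned by a deterministic center-star
strategy: the longest sequence is the center, every other sequence is
aligned pairwise against it, and the pairwise alignments are merged on
center coordinates (insertions between the same center positions share
columns, left-aligned; row order is input order). For two sequences this
is exactly the optimal pairwise alignment. A pluggable external aligner
could replace this step, but every shipped result and test uses the
internal one — determinism is the point.

Cytb is protein-coding, so an internal gap run whose length is not a
multiple of three is a frameshift artefact rather than biology. Each
such position is filled with the column consensus when all non-gap
characters in the column agree, and with `N` when the column shows
diversity; in-frame runs (3, 6, 9, …) and terminal gaps are untouched.
Reading the frame rule as "not a multiple of 3" rather than literally
"not exactly 3" is deliberate: a 6-nt run is a routine two-codon
deletion, and filling it would destroy real signal. A `strict_three`
flag switches to the literal reading for comparison. Consensus is taken
from conspecific columns only, not from the reference — the reference
is another species and would bias fills toward it. The operation is
idempotent and never alters a non-gap character.

Ambiguity trimming converts leading and trailing runs of non-ACGT
characters (all IUPAC ambiguity codes, not just N) into terminal gaps;
internal ambiguities stay and are later removed per pair by pairwise
deletion.

## Cross-species comparisons

Within-species distances are measured on the species alignment.
Cross-species distances are measured on reference-coordinate
projections: each mapped sequence contributes the character aligned to
every reference position in its span (insertions relative to the
reference are dropped, deletions become gaps). Projection avoids
genus-level re-alignment artifacts and keeps every cross-species pair
comparable on a fixed coordinate system at the cost of ignoring
insertions shared by a genus but absent from the reference — a minor
loss for a conserved protein-coding locus.

## Coverage and summaries

Per reference position, the profile counts sequences and distinct
species with a non-missing (A/C/G/T) base. The best region of a given
window length maximises, lexicographically, the window *minimum* of
species coverage, then of sequence coverage, tie-broken leftmost —
species coverage is the stated priority of the search and the window
minimum guarantees the region is usable end to end. The scan is
exhaustive over all start positions. Summary statistics report sequences
per species and species per genus/family with medians and quartiles by
linear interpolation between order statistics (R's default percentile
definition; "interquartile range" admits several conventions, so the
choice is stated rather than implied).

## The synthetic benchmark

`simulate_records()` generates repository-like corpora with planted,
bookkept errors. Species ancestors are the reference mutated at
`inter_div` per site; conspecific sequences are the ancestor mutated at
`intra_div` (independent per-site substitutions, uniform alternative
base, no indels except planted ones — chosen so expected p-distances
stay analytic: two mutants of one ancestor differ at a site with
probability 2p(1−p) + (2/3)p²). The defaults are the package's benchmark
conditions: 10 genera × 3 species × 8 sequences, `intra_div` = 1%,
`inter_div` = 8% — conspecific spread well below the 3% threshold and
species separation well above it, the regime in which a fixed threshold
is meaningful for this marker.

Planted error classes mirror the error taxonomy the pipeline reports:
misidentifications (label swaps), backward reads, RefSeq twins,
open-nomenclature names, terminal N runs, embeddings into random 16-kb
backgrounds, and single-nucleotide frameshift deletions.
Misidentifications are planted as *cross-genus* relabelings: the
intrageneric screen by design also flags the innocent nearest partner of
a within-genus mislabel, so only cross-genus plants admit an exact
precision/recall accounting; the within-genus case is exercised
separately in the unit tests of `flag_intrageneric()`.

What the generator does **not** emulate: phylogenetic structure
(coalescent or otherwise), rate heterogeneity across sites, real indel
processes, sequencing-error profiles, or the long-tailed abundance
distribution of real repositories. Passing the planted-recovery
benchmarks therefore shows the machinery is correct under clean
separation, not that a 3% threshold is optimal for any particular real
clade — the threshold remains a scientific input.

Problem sizes used by the shipped tests and the acceptance script —
240-record benchmarks over 10 seeds for misidentification recovery,
504 records with 40 planted backward reads for orientation, 1,000
random pairs for the distance oracle — were chosen as the smallest sets
that exercise every code path with exact expected outcomes.

## Numerical and degenerate-input choices

* All threshold comparisons happen on exact rational values; percentages
  are rounded to two decimals only in written reports.
* Alignment scores are integers; ties between strands give
  `orientation = "undetermined"` rather than an arbitrary pick.
* Single-sequence species are "unassessable", reported as such, and
  never flagged.
* Empty inputs produce empty outputs and a zero-count manifest, not
  errors; only configuration and I/O problems abort a run.
* RefSeq deduplication normalises case and terminal N padding before
  comparing sequences, drops an `NC_` record only when an identical
  same-species partner is retained, and keeps one copy when all
  identical copies are RefSeq — unique data are never lost.
* The run manifest reconciles counts exactly:
  input = curated + flagged-excluded + duplicates + uncertain +
  unmappable.

## Known limitations

* Center-star alignment is O(n·L²) per species and not phylogeny-aware;
  for the small conspecific sets this pipeline aligns it is accurate and
  deterministic, but it is not a general-purpose MSA engine.
* Projection-based cross-species distances ignore insertions relative
  to the reference.
* The local-ends mapping accepts any block above the identity floor and
  minimum span; a chimeric record whose halves map to disjoint reference
  intervals is reported by its best half only.
* Verdicts on flagged sequences are out of scope by design — the tool
  produces the candidate list and the evidence, never the judgement.
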