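---
title: "Plastome structure, repeats and RNA editing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome structure, repeats and RNA editing: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plastedit)
```

This vignette explains what each stage of the package computes, the
assumptions behind it, the parameters that matter, and the places where a
genuine design choice had to be made. It states no empirical numbers beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The biological setting

Plastid genomes of land plants are circular molecules of roughly 120–200 kb
with a conserved quadripartite architecture: a large and a small single-copy
region (LSC, SSC) separated by two identical inverted repeats (IRa, IRb).
Lineages with reduced dependence on photosynthesis — parasitic plants, and
to a lesser degree carnivorous ones — tend to lose NAD(P)H-dehydrogenase
(*ndh*) genes, introns and RNA-editing sites, accumulate repeats, and
rearrange gene order. Quantifying those signals requires a consistent
pipeline over annotated genomes and transcriptome alignments; that pipeline
is what this package implements.

Internally all coordinates are 0-based half-open; everything serialized
(GenBank, GFF3, TSV) is 1-based inclusive, matching the conventions of the
formats themselves. Sequences are restricted to `{A,C,G,T,N}`; other IUPAC
ambiguity codes are rejected at construction because every downstream
algorithm (pileup, repeat seeding, inverted-repeat extension) is defined
over that alphabet, and `N` is treated as matching nothing anywhere.

## Inverted-repeat detection

`find_inverted_repeat()` looks for the maximal pair of disjoint, exactly
reverse-complementary intervals on the circle. The search seeds on 21-mers
shared between the sequence and its reverse complement and extends each
seed maximally with exact matching. Choices worth recording:

* **Exact matching, mismatch tolerance zero.** Plastid IR copies are kept
  near-identical by copy correction, and a single IR length per genome is
  the quantity of interest. Detecting degraded IRs with indels is out of
  scope.
* **Circularity via the doubled sequence.** Matches longer than the genome
  are discarded; every circular interval has a linear representation on the
  doubled string. Rotating the input by any offset leaves the detected IR
  length unchanged (tested).
* **Seed stride.** Seeds are sampled every `min_len/2` positions, which
  guarantees at least one seed inside any true IR copy of length
  `>= min_len` (default 1000 bp, floor 100 bp).
* **Tie-break.** Among equal-length candidate pairs the smallest start
  coordinate wins, for determinism.
* **Naming.** The longer single-copy gap is the LSC by definition; walking
  the circle in sequence orientation gives LSC, IRb, SSC, IRa.

The accounting identity `total = 2*ir + ssc + lsc` is exposed separately as
`quadripartite_accounting()` since it is a useful check against published
component lengths.

## Repeat quantification

Repeat content is computed on the genome with one IR copy excised
(`remove_one_ir()` keeps LSC + IRb + SSC), because otherwise the two
near-identical ~20–50 kb IR copies dominate any repeat statistic.

`find_dispersed_repeats()` is an ungapped seed-and-extend self-alignment on
both strands: exact shared words (default length 7) seed X-drop extensions
scored +1/−2, and each maximal hit gets a Karlin–Altschul E-value
`E = K·n²·exp(−λ·S)` with the effective search space fixed at `n²`. λ is
solved numerically from the score system under uniform base composition
(≈1.333 for +1/−2); K is set to 0.621, the standard ungapped value for this
score pair. Hits above the E-value ceiling (default 1e-6) are dropped, the
trivial self-identity diagonal is excluded, and symmetric duplicates are
reported once. Reported repetitive bp is the union of all positions covered
by at least one passing hit interval, with *both* members of each pair
contributing — the only convention under which a repeat-rich plastome can
plausibly have tens of percent of repetitive sequence. Because X-drop
extension ends at the best-scoring column, a hit can overrun an exact
planted duplication by a few chance-matching flank bases; the closed-loop
tests allow for this.

Because the percentage denominator is genuinely ambiguous in comparative
tables (full genome vs IR-reduced length), `repeat_content_summary()`
reports both: `dispersed_pct` over the analyzed (IR-reduced) length and
`dispersed_pct_full` over the full genome. Dispersed and tandem coverages
are reported independently, plus their union (`combined_bp`), since whether
published dispersed and tandem counts overlap is usually unstated.

`find_tandem_repeats()` enumerates maximal runs of at least two exact
copies of a primitive unit of 2–40 bp with total span ≥ 20 bp, via
lag-u self-comparison and run-length encoding. The reported unit is the
lexicographically least rotation of the primitive unit (determinism); runs
contained in a reported run with a shorter primitive unit are suppressed;
the span includes a partial terminal copy where the periodicity continues.
An exhaustive oracle that tests every (start, unit-length) pair by direct
substring comparison is kept in the test suite and must agree exactly on
sequences up to 5 kb.

## Editing-site calling

`build_pileup()` implements the read-filter cascade: unmapped, secondary
and supplementary alignments are dropped; soft-clipped reads are dropped
when `forbid_softclip` (default on); per-read identity is computed directly
against the genome as matches / aligned columns with inserted and deleted
columns counted as mismatches — a conservative denominator chosen because
published filter descriptions rarely define it — and reads under 98%
identity are dropped. This identity filter is what keeps reads of
mitochondrial or nuclear plastid-like copies out of the pileup. Overlapping
mate pairs are counted as two observations (naive pileup), switchable via
`dedup_overlapping_mates`.

`call_editing_sites()` reads the thresholds strictly: depth ≥ 10, alt
fraction **strictly greater than** 0.10 over all passing reads, alt reads
**strictly greater than** 3 (i.e. at least 4). A site must lie in an
annotated CDS with C on the coding strand: reference C with T alternates on
plus-strand genes, reference G with A alternates on minus-strand genes. The
frequency estimator is the C-versus-U ratio `alt/(ref + alt)`, excluding
other bases. Library strandedness is not assumed; positions inside CDSs on
both strands are reported for both genes with a `dual_strand` flag. CDSs
whose spliced length is not divisible by 3 are flagged with a warning and
skipped rather than called.

## Editing-site prediction

`predict_editing_sites()` reconstructs a conservation-score predictor: the
CDS translation is globally aligned (affine gaps, BLOSUM62, gap open 10 /
extend 0.5) to every homolog in a protein panel; for each C whose C→U edit
changes the residue without creating a stop, the score is the fraction of
informative homologs (non-gap at the column) carrying the *edited* residue.
The 0.7 default threshold is the conventional operating point. The fraction
definition is the simplest score consistent with published score values
lying on a 0–1 grid of homolog fractions; numerical parity with any
specific external predictor is not claimed, only threshold-level behaviour
(unanimous panels score 1.0, a 7-of-10 panel exactly 0.7). Edits creating a
stop are excluded; edits creating a start codon are out of scope.

## Gene content and gene order

`classify_gene_status()` calls a gene intact iff some annotated copy starts
with ATG or GTG (the plastid norm for alternative initiation), ends with a
stop, has spliced length divisible by 3 and no internal stop; a
frameshifting insertion (e.g. 22 bp) therefore fails the mod-3 test without
needing any alignment. Annotated `/pseudo` copies count as pseudogenes.
"Unique genes" count IR-duplicated copies once. Because the line between
"presumably intact" and functional is editorial (long N-terminal extensions
and the like), classification is by ORF integrity only, with an optional
`reference_length` flagging intact genes deviating more than 25%.

Gene-order comparison is deliberately reduced to a scalar:
`breakpoint_distance()` counts signed circular adjacencies of one order
absent from the other, with `(x, y)` identified with `(−y, −x)`. This is
zero iff the orders are equivalent up to rotation and reflection with sign
flip, and a single inverted block costs exactly 2. Full synteny-block
detection adds nothing testable at this scale.

## The simulator and what it does (and does not) emulate

`simulate_plastome()` assembles LSC + IRb + SSC + IRa with IRa the exact
reverse complement of IRb, places the planned genes (CDS built codon-wise:
ATG start, non-stop interior, TAA stop; introns as random spacers;
minus-strand genes reverse-complemented; IR-region genes duplicated and
strand-flipped in IRa), plants dispersed-repeat copies and tandem arrays in
random ≥ 50 bp spacers, applies frameshifting insertions (default 22 bp)
for configured pseudogenes, and overwrites planned codons for editing sites
(default `CCA`, edited at the second position to give P=>L). One detail is
deliberate: the single-copy bases flanking the IR junctions are nudged if
they happen to be complementary, so the planted IR is exactly the maximal
reverse-complement pair and recovery can be asserted to the base.

`simulate_rnaseq_reads()` emits pre-aligned, coordinate-sorted SAM
(single-end, full-match CIGAR, NM/MD tags): read starts uniform within each
exon, edited bases carried with probability equal to the planted frequency
(reverse-complemented into reference coordinates for minus-strand genes),
uniform substitution errors elsewhere. The default study-scale conditions
are 50× coverage, 100 bp reads and a 0.1% error rate; the full-size default
geometry is an 80 kb LSC, 20 kb IR and 15 kb SSC (135 kb genome), with
smaller geometries used in the test matrix to keep the suite fast (the
closed-loop suite runs ten ~13–16 kb configurations plus one 135 kb
genome).

What the simulator does **not** emulate: realistic transcript abundance
(uniform coverage only), indel sequencing errors, quality-score
distributions, RNA degradation, mapping ambiguity, and compositional bias
of real plastomes. Passing the closed-loop tests therefore demonstrates
correctness of the algorithms under clean conditions — coordinate and
strand bookkeeping, threshold semantics, estimator behaviour — not
robustness to every artifact of real libraries.

`simulate_homolog_panel()` generates homologs carrying the edited residue
at flagged positions with a configurable conservation probability and a 5%
background mutation rate elsewhere; by the law of large numbers the
predictor's score converges to the conservation level (tested at panel
size 1000).

## Numerical and degenerate-input choices

* Karlin–Altschul K fixed at 0.621 (+1/−2 ungapped); λ from `uniroot` on
  the score-system identity. Only threshold behaviour depends on these.
* Peptide-repeat blocks (`find_peptide_repeats()`): membership requires
  70% per-window identity to the running column-majority consensus; within
  a candidate region every phase of the unit is grown and the phase
  maximizing matches-minus-mismatches against the final consensus wins, so
  exact repeats report the unit itself, never a rotation, and the unit
  length is always the primitive period. Overlaps across unit lengths are
  resolved by the same score. A partial terminal copy counts fractionally
  when its consensus-matching prefix covers at least half the unit; with
  degenerate copies whose mutations straddle the copy boundary, the winning
  phase may legitimately be a rotation of the nominal unit.
* Editing thresholds are strict inequalities (`> 10%`, `> 3 reads`),
  following the natural reading of "more than"; the boundary cases are
  pinned by exact tests.
* Empty inputs, absent IRs (`NULL` partitions), feature-less FASTA records
  and genes absent from annotation all flow through without special-casing
  by the caller; contract violations (reference-id mismatch, non-C edit
  positions, plan overflow) raise errors naming the offending object.
* GenBank support is intentionally minimal — LOCUS/FEATURES/ORIGIN with
  `join`/`complement` locations and the `gene`/`pseudo` qualifiers the
  package consumes; one origin-spanning feature is normalized by rotating
  the sequence (the rotation is recorded on the record). Rich qualifier
  preservation is a non-goal.

## Known limitations

* Dispersed-repeat search is ungapped; diverged repeats interrupted by
  indels are reported as separate hits or missed.
* The editing caller does not deduplicate overlapping mates by default and
  ignores library strandedness, which can double-count fragments and
  cannot assign a site in dual-strand CDS overlaps to one gene.
* The predictor's score is a reconstruction; its absolute values should be
  compared across panels with the same composition, not across tools.
* IR detection assumes a single dominant IR pair; genomes with multiple
  equal-length long inverted duplications return whichever pair starts
  first.
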