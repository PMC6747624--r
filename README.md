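# plastedit

Comparative structural and post-transcriptional analysis of plastid
(chloroplast) genomes, built for the kind of questions raised by
heterotrophic and carnivorous plant lineages: how large is the inverted
repeat, how much of the genome is repetitive once one IR copy is set aside,
which genes are lost or pseudogenized, and which C→U RNA-editing sites are
actually used in transcripts.

The package covers six analysis stages, each a plain function over a small
set of containers, plus a ground-truthed simulator so that the whole
pipeline is testable without any external data:

| Stage | Functions |
|---|---|
| Annotated genome I/O (GenBank, FASTA, GFF3) | `read_plastome()`, `write_genbank()`, `extract_cds()` |
| Quadripartite structure (LSC/IRb/SSC/IRa) | `find_inverted_repeat()`, `quadripartite_accounting()` |
| Dispersed + tandem repeat content | `remove_one_ir()`, `find_dispersed_repeats()`, `find_tandem_repeats()`, `repeat_content_summary()` |
| C→U editing calling from RNA-seq (SAM) | `build_pileup()`, `call_editing_sites()` |
| Conservation-score editing prediction | `predict_editing_sites()` |
| Gene content, introns, gene order | `classify_gene_status()`, `compare_gene_sets()`, `breakpoint_distance()` |
| Peptide tandem repeats in ORFs | `find_peptide_repeats()` |
| Synthetic data with truth ledgers | `simulate_plastome()`, `simulate_rnaseq_reads()`, `simulate_homolog_panel()` |

## The methods in brief

**Inverted repeat.** The quadripartite partition is found as the maximal
pair of disjoint, exactly reverse-complementary intervals on the circular
sequence (21-mer seeding against the reverse complement, maximal exact
extension, search on the doubled sequence for circularity). Total length
obeys `total = 2·IR + SSC + LSC`; for example `2·25,190 + 19,208 + 87,049 =
156,637` bp.

**Repeats.** Dispersed repeats come from an ungapped seed-and-extend
self-alignment (word size 7, +1/−2 scoring, X-drop 20) with Karlin–Altschul
E-values over a search space of `n²` and a 1e-6 ceiling; reported content is
the union of all positions in passing hits, both copies counting, after one
IR copy is removed. Perfect tandem repeats are maximal runs of ≥ 2 copies of
a primitive 2–40 bp unit spanning ≥ 20 bp.

**Editing caller.** Reads are filtered (no soft clips, ≥ 98% identity with
indel columns counted as mismatches); a site is called iff it lies in a CDS
with C on the coding strand, depth ≥ 10, alt fraction > 10% and alt reads
> 3. The editing frequency is the C-versus-U ratio among passing reads.

**Editing predictor.** For each C whose C→U edit changes the encoded
residue, the score is the fraction of informative homologs (global
alignment, BLOSUM62) carrying the edited residue at that column; sites with
score ≥ 0.7 are predicted.

## Worked example

Simulate an annotated quadripartite plastome with planted edits and a
frameshifted gene, then run the pipeline end to end:

```r
library(plastedit)

cfg <- sim_config(seed = 7, lsc = 8000, ir = 2500, ssc = 3000,
  editing_plan = list(list(gene = "atpF", codon_index = 31, frequency = 0.8),
                      list(gene = "ndhD", codon_index = 100, frequency = 0.9)),
  pseudogenize = list(list(gene = "ccsA", indel = 22)))
truth <- simulate_plastome(cfg, out_dir = "sim_demo")

part <- find_inverted_repeat(truth$record)
part
#> <quadripartite_partition> total 16,000 bp = LSC 8,000 + IR 2,500 x2 + SSC 3,000

repeat_content_summary(truth$record, part)
#> <repeat_report> SIMPLAST000007: analyzed 13,500 bp | dispersed 630 bp
#>   (4.67% of analyzed, 3.94% of genome) | tandem 30 bp

sam <- file.path("sim_demo", "reads.sam")
simulate_rnaseq_reads(truth, sam)
sites <- call_editing_sites(build_pileup(sam, truth$record), truth$record)
sites[, c("gene", "codon_index", "codon_display", "aa_change",
          "frequency", "depth", "alt_reads", "strand")]
#>   gene codon_index codon_display aa_change frequency depth alt_reads strand
#> 1 atpF          31           CcA      P=>L 0.8000000    50        40      +
#> 2 ndhD         100           CcA      P=>L 0.8039216    51        41      -

classify_gene_status(truth$record, "ccsA")
#> <gene_status> ccsA: pseudogene (1 copy, 0 introns)
```

The partition recovers the planted region lengths exactly; the dispersed
union (630 bp) is the two planted 300 bp copies plus a few chance-matching
flank bases; both planted edits are called — the minus-strand `ndhD` site
appears as G→A in reference coordinates but is reported as a C→U event with
its codon (`CcA`, P=>L) and frequency close to the planted values (0.8 and
0.9 at ~50× depth); and the 22 bp insertion in `ccsA` is classified as a
frameshift pseudogene.

The same functions accept real data: `read_plastome("genome.gb")` for a
GenBank flat file, a SAM file of transcriptome alignments for
`build_pileup()`, and a protein FASTA panel for `predict_editing_sites()`.

A thin command-line wrapper is included at `inst/cli/plastedit.R`
(subcommands `quadripartite`, `repeats`, `tandem`, `editing-call`,
`editing-predict`, `gene-compare`, `orf-repeats`, `simulate`, `report`).

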