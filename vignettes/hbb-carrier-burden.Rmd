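---
title: "Methods: consequence annotation and carrier burden for HBB cohort variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consequence annotation and carrier burden for HBB cohort variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbbcohort)
```

# Scope and model

`hbbcohort` analyses coding variation of a single-transcript protein-coding
gene — in practice the β-globin gene *HBB* — across a multi-population
diploid cohort. The analysis has three stages, each exposed as tibble-first
functions and together as `run_pipeline()`:

1. consequence annotation of VCF variants against a strand-aware gene model;
2. aggregation of categorical pathogenicity evidence into per-variant
   verdicts;
3. allele-frequency, carrier-burden and Hardy–Weinberg summaries.

The package assumes exactly one transcript per gene, a complete genotype
matrix (no missing calls), and biallelic records. UTR and regulatory
annotation, multiple transcripts, phase, linkage and inbreeding corrections
are out of scope.

# Gene model and coordinate arithmetic

A `gene_model()` stores coding-exon intervals in 1-based inclusive genomic
coordinates (the convention of GFF3 and VCF, the two formats it touches),
on either strand. Offsets along the spliced CDS are 0-based in transcript
orientation; for a minus-strand gene, transcript order runs from the highest
genomic coordinate downwards. `genomic_to_cds()` and `cds_to_genomic()` are
mutual inverses on the CDS; the tests verify this exhaustively for the
packaged gene and for randomly generated ones.

Residue numbering counts the initiator Met as residue 1. This matches the
labeling that clinical sources increasingly use for β-globin (the sickle
substitution appears as Glu7Val rather than the classical Glu6Val) and
keeps formatted protein changes directly comparable with database entries.

The packaged HBB-like model places three coding exons of 92/223/126 nt
(441 nt CDS: 146 residues plus terminator) with introns of 130 and 850 nt
on the minus strand of an HG19-scale chromosome-11 window. The published
survey this fixture reconstructs gives variant positions but not exon
boundaries; the boundaries here are fixed by the splice-window
classifications the survey reports — a donor lesion two intronic bases past
exon 1, an acceptor lesion immediately before exon 2, and splice-region
substitutions on the terminal exonic bases — which pin the exon-1/intron-1
and intron-1/exon-2 junctions exactly, and by the codon indices of the
coding variants, which then determine every other boundary. Codon 31 spans
the first junction (two bases in exon 1, one in exon 2), as the
splice-region missense at the first base of exon 2 requires.

## Splice windows

Window sizes follow the convention of standard effect annotators and are
configurable in `splice_windows()`: the donor core is the first 2 intronic
bases after an exon (transcript orientation), the acceptor core the last 2
intronic bases before an exon, and the splice region covers exonic bases
1–3 and intronic bases 3–8 from a junction. Donor/acceptor terms co-occur
with `intron`, splice-region terms with the coding term of the base (or
with `intron` for intronic hits); splice terms never appear alone.

# Consequence classification

For a coding SNV the annotator compares the reference and alternate codons
after strand adjustment: same residue → `synonymous`; terminator introduced
→ `stop_gained`; otherwise `missense`. A length-changing coding variant
whose net length change is not a multiple of 3 is a `frameshift`.

Frameshifts are labeled at the first codon whose spliced-CDS base differs
between reference and alternate. Anchored VCF deletions make this the
natural choice: the CAAAG→C deletion of the packaged cohort removes four
cDNA bases starting at the third base of codon 42, so the first differing
CDS base falls in codon 42 and the change formats as `Phe42fs`. Locating
the first *differing* base (rather than the first *deleted* coordinate)
also makes the label well defined when a deletion sits in a repeat run,
where the deleted-coordinate representation is ambiguous.

In-frame length changes are classified by whole-protein comparison (equal
proteins → `synonymous`, premature terminator → `stop_gained`, otherwise
`missense` at the first differing residue); residue-level naming of
in-frame indels beyond this is not attempted. A substitution that destroys
the terminal stop codon is reported as `missense` at the terminator
position; stop-loss read-through semantics are out of scope, and the random
generators used in the tests leave the stop codon untouched.

## The independent oracle

`classify_by_full_translation()` derives the same consequence without any
CDS offset arithmetic: it applies the edit to the entire contig, shifts the
exon boundaries through the edit (a start boundary inside a deleted run
snaps to the first surviving base, an end boundary to the last base before
the run), re-splices, re-translates and diffs whole proteins. The
acceptance suite checks agreement between the two routes on over 1,000
variants drawn across 25 seeded random gene systems (1–3 exons, 30–60 codons, both
strands; coding, intronic and intergenic SNVs plus frameshift-length
deletions), as well as on all 20 packaged variants. Strand-mirror
invariance — reverse-complementing the contig and flipping the model leaves
every consequence unchanged — is checked on the same systems via
`mirror_gene_system()`.

# Evidence aggregation

Evidence arrives as one categorical label per source per variant, over the
vocabulary `Damaging`, `Probably damaging`, `Benign`, `Other`,
`not-evaluated`. `normalize_label()` maps these to `damaging`, `benign`,
`uninformative`, `absent`. `Other` is deliberately *uninformative* rather
than benign: rows carrying `Other` database entries resolve correctly on
their remaining labels, and treating a catch-all clinical annotation as
exculpatory would be unsound.

The combination rule is the package's own design, since the source survey
names its four evidence classes (ClinVar, dbSNP, HbVar, and the predictors
jointly) without stating how they combine:

* each class (databases; predictors) takes a **strict majority** of its
  informative labels — ties and label-free classes abstain (`NoCall`);
* two agreeing classes, or one call plus one abstention, give the verdict;
* two abstentions give `NotEvaluated`; disagreement gives `Conflict`.

Pure-synonymous variants are excluded from review (`NotEvaluated`),
mirroring the survey's protocol. On the packaged evidence table this rule
reproduces 15 of the 16 published conclusions. The residual row, Pro6Ser
(rs33912272), is published as Conflict although all of its informative
labels except one predictor are benign; no single rule can produce both
that row and the published Damaging for Arg31Ser (which tolerates one
benign database). Rather than guess the survey's intent, the package ships
the computed Benign and an explicit one-row override table
(`hbb_overrides()`), applied transparently with `overridden = TRUE`. A
stricter any-disagreement rule (`strategy = "unanimous"`) is available for
sensitivity analysis. Verdicts are invariant under source permutation
within a class and under insertion of uninformative or absent labels, and
promoting a benign predictor label can never demote a Damaging verdict —
all property-tested.

# Burden statistics and display conventions

With *N* diploid samples, per-variant allele counts add 1 per heterozygote
and 2 per homozygous-alternate genotype (supported though absent from the
packaged cohort, whose carriers are all heterozygous). The cohort summary
reports carriers, the pure-synonymous / missense-only / non-synonymous /
deleterious carrier partitions, the pooled mutant-allele frequency
*q* = Σ alt alleles / 2*N*, and the Hardy–Weinberg projection *q*²: under
random mating, the probability that an offspring draws two mutant alleles —
homozygous or compound heterozygous for the pooled class. The deleterious
projection *q_d*² uses only Damaging-verdict alleles. Pooling all mutant
alleles into one frequency is the survey's implicit model; a per-variant
Σ*q_i*² refinement would ignore compound heterozygotes and is intentionally
not the default.

Two display conventions coexist in the published tables, and the package
reproduces both while always retaining exact values: cohort-level
frequencies and percentages are **truncated** (209/2504 = 8.346…% prints
8.34%; 137/5008 = 0.027356… prints 0.02735, where rounding would give
0.02736), whereas per-population table cells are **rounded** to 4 decimals
(17/1322 → 0.0129). `allele_frequency(..., display = "paper")` and
`render_tables(style = "paper")` implement these; `style = "exact"` emits
full precision. Truncation guards against binary floating error with a
1e-9 epsilon before flooring.

# The synthetic cohort generator

`build_reference()` fills a genomic window with seeded-random bases, then
satisfies three constraint families jointly: variant reference alleles pin
contig bases; explicit base pins fix canonical GT/AG splice dinucleotides
and junction-codon bases; codon constraints force required residues
(initiator Met and the terminal stop always; no internal stops ever). A
codon is chosen uniformly among the codons compatible with its residue
constraint and pinned bases; incompatible constraints abort with a spec
error. `simulate_cohort()` places each carrier in its population without
replacement, one variant per carrier — the packaged survey's carrier counts
sum exactly to its carrier individuals, so double heterozygotes do not
occur — and emits unphased `0/1` genotypes (the analysis never uses phase).

The packaged cohort uses super-population sizes 661/347/504/503/489
(AFR/AMR/EAS/EUR/SAS). The survey never prints them; these are the
phase-3 sizes, and they back-derive from the internally consistent
published frequency cells (e.g. 17 alleles at 0.0129 ⇒ 2 × 661). Two known
inconsistencies in the source tables are handled explicitly rather than
reproduced: the AFR/AMR per-population frequency cells of the sickle allele
are transposed relative to their counts, so counts are stored as ground
truth and frequencies recomputed; and the rs35578002 row is labeled with an
amino-acid string (Glu30Gly) that contradicts its own consequence class
("splice region and synonymous") and the lesion's identity — the fixture
encodes reference codon 30 as Gly, making the published G/T change
synonymous, and keeps the published string only as metadata.

What the generator does *not* emulate: linkage disequilibrium, realistic
site-frequency spectra outside the specified variants, mutation-rate
heterogeneity, sequencing error, missing genotypes, or multi-allelic sites.
Passing tests therefore demonstrate correctness of the arithmetic and the
rules on exactly specified cohorts, not robustness to the messiness of raw
call sets.

# Determinism and problem sizes

Every random choice flows through a single integer seed
(`withr::with_seed`), and identical seeds give byte-identical output files;
the pipeline itself is deterministic given its inputs. All published
quantities derived downstream of the generator are invariant to the seed,
because only filler bases and carrier placement are random.

The checked problem sizes are chosen so the whole suite runs comfortably on
a laptop: 25 random gene systems × 45 variants for the annotator/oracle
equivalence, 10 systems for round-trip and mirror properties, and 10^5
simulated offspring for the random-mating check, which agrees with *q*²
within three binomial standard errors.

# Known limitations

* One transcript per gene; no canonical-transcript selection.
* Indel naming is limited to the frameshift/non-frameshift distinction.
* Verdicts are categorical; predictor scores, ACMG criteria and live
  database queries are out of scope.
* Frequency estimates carry no confidence intervals; Hardy–Weinberg
  projections assume random mating and no population structure, which
  understates risk where carrier alleles cluster geographically.
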