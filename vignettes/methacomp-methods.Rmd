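---
title: "methacomp: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methacomp: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methacomp)
```

## Scope

`methacomp` implements the comparative-genomics toolbox used to
characterize the Methanomassiliicoccales, the seventh order of methanogenic
archaea: gut-associated, H2-dependent methylotrophic methanogens that lack
the CO2-reduction pathway and decode the amber codon as pyrrolysine (Pyl, O)
in their methylamine methyltransferases. Six analyses are covered — genome
feature statistics, amber-readthrough (Pyl protein) prediction,
ORB-motif replication-origin mapping, de novo CRISPR array detection,
best-hit core-genome orthology, and phyletic-pattern classification of
methanogenesis markers — together with a synthetic annotated-genome
generator that plants every signal with a machine-readable truth record, so
each detector can be scored against ground truth.

## Genome representation and translation

Genomes are uppercase DNA strings over `{A,C,G,T,N}` with a circular or
linear topology; annotations are 1-based inclusive, strand-aware intervals
(the GenBank/GFF3 convention, so coordinates move between formats without
shifting). Features wrapping the origin of a circular chromosome are stored
as two segments sharing one id, listed in translation order. Translation
uses NCBI table 11; `translate_cds(nt, readthrough_amber = TRUE)` decodes
TAG as `O` and continues, while TAA/TGA always terminate; codons containing
`N` give `X`. GFF3 I/O goes through `rtracklayer`; the GenBank flat-file
reader is a minimal in-package parser (no installed package reads the
format) covering LOCUS/FEATURES/ORIGIN with `complement()`/`join()`
locations.

## Homology engine

All protein homology calls use in-package Smith–Waterman local alignment
(`Biostrings::pairwiseAlignment`, BLOSUM62, affine gap penalties 11/1).
Two explicit statistics replace search-tool output:

* **identity** = matches / aligned columns (gap columns included), in %;
* **coverage** = aligned query residues / query length, in %.

Score ties are broken by lexicographic subject id, which makes every
best-hit result independent of input order (tested). This engine is exact
at the scale of the package's analyses; for multi-megabase proteome
screens a dedicated search tool would be substituted behind the same
interface.

## Synthetic genomes: the stated world

`synth_config()` defaults state the envelope of the three sequenced
genomes: ~2 Mbp, GC 41–61% (default 0.55), coding density 0.89, mean CDS
900 bp, stop usage configurable per genome (the three organisms span amber
stop fractions from ~1.6% to ~11.3%). Choices worth recording:

* **Background** is order-0 (iid) sequence at the configured GC — the
  simplest model that controls GC and coding density.
* **Genes** are a start codon (ATG/GTG/TTG at 84/11/5%), GC-weighted
  sense codons (no in-frame stops by construction), and a stop codon.
  Gene lengths follow a gamma distribution (shape 1.8) matching the
  observed mean ≈ 900 bp with SD ≈ 670 bp; the last background gene is
  resized so total gene cover hits the density target to within a few bp.
* **Stop codons** are allocated by largest-remainder quota and then
  shuffled, so realized usage matches the configured fractions to less
  than one codon for any gene count — the ±3-point tolerance holds by
  construction rather than in probability.
* **Back-translation** samples synonymous codons proportionally to their
  iid-base probability at the target GC, so GC-dependent statistics (e.g.
  GC3) respond to the configured GC across the 41–61% range.
* **Collision screening**: background segments (intergenic gaps and
  background genes) are resampled until they contain no exact copy of a
  planted CRISPR repeat and no 22-mer within Hamming distance 1 of a
  planted ORB core, on either strand. This makes planted-recovery tests
  exact. Junction-spanning collisions are not screened; at the scales used
  their probability is negligible, and a fixed seed makes every test run
  identical anyway.
* **Determinism**: all randomness runs under `set.seed(seed)` with the
  generator kinds pinned; the caller's RNG state is saved and restored.

What the generator does **not** emulate: phylogenetic structure within
proteomes, indel evolution, codon usage beyond GC weighting, mobile
elements, leader sequences of CRISPR arrays, and real intergenic signal
(promoters, terminators). A green planted-recovery test therefore
establishes detector correctness on clean signals with calibrated
composition — not performance on the full messiness of real genomes.

### The planted Pyl locus

`plant_pyl_locus(ref, p)` emits a CDS encoding `ref[1..p]` plus TAG,
followed in frame by `ref[(p+1)..n]` and an ochre stop. The readthrough
fusion is `ref[1..p] + O + ref[(p+1)..n]`: the pyrrolysine is *inserted
after* position `p`, so the fusion has length `n + 1` with `O` at
`p + 1`. (A real Pyl protein carries O *in place of* a residue; the
insertion convention keeps the upstream segment, extension and fusion
lengths in an exact arithmetic relationship that the detector's invariants
check. Both segments remain full-identity matches to the reference, so
detection is unaffected.)

## Amber readthrough detection

For every TAG-terminated CDS the detector translates the in-frame 3'
flank up to (excluding) the next stop, and emits a candidate iff the
upstream protein and the extension have the *same best* qualifying hit in
the reference database. Defaults: identity ≥ 30%, coverage ≥ 50% of each
segment, extension ≥ 15 aa. The coverage bound is 50% rather than the 80%
used for whole-protein orthology because both segments are protein
*fragments* of their shared homolog. A `shared` mode (any common
qualifying hit) is provided since the original wording does not force the
hits to be best hits; `best` is the default. If the extension itself ends
at another TAG the fusion may iterate (default cap 2 ambers; known Pyl
proteins have one).

Cassette detection (`detect_pyl_cassette`) makes whole-gene homology calls
for pylS/B/C/D and therefore additionally requires the alignment to cover
the threshold fraction of the *reference*; without this, short random CDS
can cover 50% of themselves against a 400-aa reference and create false
positives (observed in testing, fixed by design). pylT is called from the
annotation: a tRNA whose product declares the CUA anticodon (CTA on the
gene); inferring anticodons from tRNA structure is out of scope.

## ORB motifs and replication origins

The scanner reports every position on both strands within a Hamming
distance (IUPAC-aware, no indels) of a degenerate core, including hits
spanning the origin of circular replicons. The default core is the 22-mer
`GTTCCAGTGGAAATGGAGGGGT` with up to 4 mismatches — the published
consensus minus its trailing base, which none of the listed motifs
supports; the hyphen in the printed consensus (fixed one-base spacer
versus alignment gap) is ambiguous, so the core is fully configurable
rather than guessed. **Spacing** between paired hits is defined as
`start(hit2) − end(hit1)`, the definition that reproduces the printed
value 39 for hits at 78–99 and 138–159; pairs are kept when
0 ≤ spacing ≤ 300 bp (published spacings: 39–256 bp). Consensus building
is per-column strict majority with ties emitted as the minimal covering
IUPAC code. Origin candidates are pairs whose midpoint lies within 10 kb
of an annotated orc1/cdc6 CDS, reported with distance and side relative
to gene orientation; singleton hits are reported by the scanner for
parity with the published unpaired motifs.

## CRISPR arrays

The de novo detector is in-package (the artifact must be self-contained):
exact 16-mers recurring with a period inside
`[dr_min + spacer_min, dr_max + spacer_max]` seed candidate arrays; runs
of ≥ `min_units` anchors are extended left and right while all instances
agree unanimously (capped by `dr_len_max` and by the shortest period);
the consensus is column majority; units beyond the 20% mismatch bound are
trimmed from the ends, and stretches violating spacer-length bounds are
split, keeping the longest compliant run. Defaults (DR 23–47 bp, spacers
20–60 bp, ≥ 3 units) bracket the published arrays (DR 31–36 bp, spacers
25–40 bp). Unanimous extension stops within one or two bases of the true
repeat boundary with only 3 units and is exact in practice from 4 units
up; with the 13-repeat arrays used in the tests recovery is exact to the
base. Spacer matching reports the exact matches/columns fraction (so a
25-of-27 match is 92.6%), with a coverage bound that keeps trivially
short perfect local alignments from masquerading as hits. DR orientation
is reported as found; no leader-based canonicalization is attempted.

## Orthology and the core genome

Best hits use the homology engine at the published thresholds — identity
≥ 30%, query coverage ≥ 80%. Orthology is best-hit-based (not reciprocal)
following the stated procedure; a reciprocal check can be composed from
two `best_hits()` calls. The three-way Venn partition assigns each
protein to one of seven cells from its two "shared with" bits; per
proteome the cell counts sum to the proteome size (a tested
conservation). The same 30/80 thresholds are applied within the trio and
against outgroups; whether the original within-trio Venn used an e-value
criterion instead is unknowable from the text, so the thresholds are
parameters of `homology_params()`.

## Marker categories

The six phyletic categories are evaluated in order 1→6 with the first
match returned (category 1 implies category 2's condition, so ordered
matching yields the most specific label):

| category | focal clade | other methanogens | other archaea |
|---|---|---|---|
| 1 | all | all | none |
| 2 | all | all | < 5% |
| 3 | all | > 90% of all methanogens | < 5% |
| 4 | none | all | none |
| 5 | none | > 90% | none |
| 6 | none | > 90% | < 5% |

">90%" and "<5%" are strict inequalities, following the wording of the
category definitions; exact-boundary rows (exactly 90% / exactly 5%)
therefore classify as the next weaker option, and an inclusive mode
(`strict = FALSE`) is provided. For categories 4–6 the "other
methanogens" fraction excludes the focal clade from the denominator
(the definitions say *other* methanogens). The classifier is verified
against an independent straight-line predicate oracle over all 4096
patterns of a 12-taxon panel.

## Numerical and degenerate-input conventions

* Coding density counts positions covered by any gene feature (CDS and
  RNA genes), overlaps once; on circular genomes it equals
  `1 − Σgaps / L` (tested identity).
* Intergenic gaps are measured after merging overlapping intervals,
  strand-ignored; abutting genes contribute a gap of 0; circular genomes
  include the wrap gap; the SD is the population SD.
* CDS without a canonical terminal stop are probed one codon downstream
  (annotations that exclude the stop codon); failing both they are
  excluded and counted separately.
* rRNA layout is "operonic" iff some 16S/23S pair is co-stranded with an
  inter-feature gap ≤ 500 bp (a typical internal transcribed spacer
  bound; configurable).
* Empty results (no hits, no pairs, no arrays, no candidates) are valid
  values everywhere, not errors; genuinely undefined statistics (fewer
  than two features for gap statistics, no CDS for stop usage) signal
  errors.

## Limitations

The alignment engine approximates, but is not, BLASTP — re-running the
published genome-scale screens would need the adapter to an external
search tool and the deposited sequences, neither of which ships with the
package. The CRISPR detector assumes repeats conserved enough to share
exact 16-mers between at least min_units instances; heavily degenerated
arrays need a smaller seed k. The generator's simplifications listed
above bound what the green test suite demonstrates.
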