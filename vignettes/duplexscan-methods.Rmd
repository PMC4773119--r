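---
title: "duplexscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{duplexscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexscan)
```

## The problem

Long non-coding RNAs (lncRNAs) can regulate other transcripts by direct
antiparallel base-pairing: masking splice signals on pre-mRNAs, occluding
miRNA target sites, creating the double-stranded 3'UTR structures that
trigger Staufen-mediated decay (SMD), and providing the duplex substrate
for A-to-I editing. `duplexscan` finds candidate lncRNA–RNA duplexes
across a transcriptome by similarity search under a wobble-aware pairing
matrix, projects them onto the genome, applies rule-based regulatory
annotation, and attaches expression-based plausibility from RNA-Seq
read-mapping summaries.

The method deliberately reduces duplex formation to sequence
complementarity scoring. Thermodynamic folding of both partners would be
more faithful but is orders of magnitude slower at transcriptome scale
and requires structural context that is unavailable for most lncRNAs;
the scoring approach trades that fidelity for tractable, calibrated
screening. Consequences of this choice are discussed under
*Limitations*.

## The duplex model and its scoring economics

A duplex is an antiparallel local alignment between a lncRNA (read
5'→3') and a target RNA (read 3'→5' under the lncRNA). Columns are
scored with a symmetric pairing matrix:

| pair | score |
|------|------:|
| G:C | +4 |
| A:U (A:T internally) | +2 |
| G:U wobble (G:T) | +1 |
| any other combination, and anything with N | −6 |

Gap runs of length $g$ cost $-20 - 8g$ (affine: opening −20, extension
−8 per base). The 4/2/1 proportions are the ones long used for RNA–RNA
interaction screening, e.g. in miRNA target-search scoring. All
sequences are normalised to the DNA alphabet on input (U→T), so RNA and
DNA sources mix freely; `N` is an ordinary mismatch, which is exactly
strong enough to stop alignments from crossing masked intron interiors
(a run of $k$ N columns costs $6k$, unrecoverable for any $k$ larger
than a few columns).

The alignment engine aligns the lncRNA against the *reversed* (not
complemented) target with this matrix, which makes a match column a
duplex base pair and keeps the wobble asymmetry intact; hits are mapped
back to the target's own 5'→3' axis. Reported alignments are extracted
greedily by descending score, masking the lncRNA and target positions
already assigned, until the score drops below the threshold; ties keep
the alignment with the smaller (lncRNA start, target start). One
consequence worth knowing: the *optimal* score is symmetric under
swapping the two roles, but when several overlapping candidates tie, the
greedy partition is resolved in role-specific coordinates and may
legitimately differ between `A vs B` and `B vs A`. The package tests
best-score symmetry on arbitrary inputs and full-set symmetry on
well-separated duplexes.

## Seeded search and its completeness guarantee

The exhaustive dynamic program (`align_duplex_exact`) is quadratic per
pair. The production path (`align_duplex_seeded`) first runs a linear
diagonal scan for a *seed*: a gapless complementary run (wobble pairs
allowed) whose pairing score reaches `seed_score`; only seed-bearing
pairs are handed to the full extension.

The default `seed_score` is derived from the matrix, not chosen by hand:
inside any alignment, consecutive pairing runs are separated by columns
that cost at least $\min(-\text{mismatch}, -(\text{gap\_open} +
\text{gap\_extend})) = 6$. If every run in an alignment scored ≤ 6, the
whole alignment could score at most 6. Hence any alignment scoring ≥ 7
must contain a run scoring ≥ 7, and a seed threshold of 7 is *complete*
for every reporting threshold above 6 — the seeded search provably
returns exactly the exhaustive search's above-threshold set. This is
verified empirically in the test suite across thresholds 30, 60 and 107.

We considered Watson–Crick-only seeds of fixed length (the classical
seed-and-extend shape). They are not completeness-safe under this
matrix: a gapless run alternating G:C and wobble columns scores 5 per
two columns and can reach any threshold while containing no long
Watson–Crick run, and short-WC-run counterexamples (e.g. a 7-long WC run
extended by two wobbles, scoring 30) occur at appreciable rates in
random sequence. The score-based seed keeps the guarantee at the cost of
pruning power: on kilobase-scale pairs a score-7 run almost always
exists somewhere, so the seed mainly protects the contract while the
speed comes from the compiled kernel. Raising `seed_score` buys
pruning back, explicitly trading completeness for speed.

## Score thresholds and chance-alignment calibration

The shipped defaults are 107 for mature-transcript search and 108 for
pre-mRNA search — the calibrated operating points corresponding to less
than one alignment expected by chance at the original transcriptome
scale. They are configuration constants, not recomputed per run.

For other search spaces `calibrate_threshold()` reproduces the
calibration empirically: it scores pairs of null sequences
(mononucleotide-composition-preserving shuffles of user sequences, or
i.i.d. uniform sequences), fits the extreme-value law
$E(s) = K\,m\,n\,e^{-\lambda s}$ by Gumbel maximum likelihood on the
per-pair score maxima, and returns the smallest integer $s$ with
$E(s)$ below the target (default: one chance alignment per search
space). Rounding is upward, i.e. conservative. Numerical notes: the fit
uses `stats::optim` (Nelder–Mead) on the Gumbel likelihood with
moment-based initialisation; scores are discrete, so the continuous
Gumbel is an approximation — adequate here because only the upper tail's
integer crossing point matters; a degenerate null (all maxima equal) is
an error rather than a silent fit. Chance-hit counts at the calibrated
threshold on independent shuffled sets fall inside the 95% Poisson
interval of the unit expectation in the test suite.

## Pre-mRNA mode and intron masking

Pre-mRNA queries are the unspliced transcript span with every intron's
interior — positions farther than 250 nt from both splice sites —
replaced by `N`. Masking substitutes rather than deletes, so the
pre-mRNA axis maps to the genome by a single strand-aware affine
transform, and the masked base count per intron is exactly
$\max(0, \text{len} - 500)$. Introns of 500 nt or less are retained
whole (the two 250-nt windows are not applied independently). An
alignment *spans a junction* when an exon–intron boundary lies strictly
inside its target interval — at least one column on each side; an
alignment ending exactly at the boundary does not count. Junction
spanning is the defining filter for lncRNA–pre-mRNA interactions.

## Genomic projection and classification

Transcript-space intervals are projected to genomic blocks through the
exon structure (split across exons in mature mode; a single block in
pre-mRNA mode), merged to unique genomic positions per chromosome and
strand, and classified:

* **cis / trans** — cis iff the two gene spans (union of each gene's
  exonic extents) overlap by ≥ 1 bp on the same chromosome on *opposite*
  strands; everything else, including same-strand overlap, is trans.
  The 1-bp quantification of "same locus" is this package's choice.
* **region class** — non-coding targets are `noncoding`; otherwise an
  interval entirely inside the 5'UTR, CDS or 3'UTR takes that class and
  a CDS+UTR straddle is `CDS_UTR`. In pre-mRNA mode the rule is applied
  on the unspliced axis with the intron-inclusive CDS span; an interval
  touching both UTRs without CDS (possible only there) takes the larger
  overlap, ties to the 3'UTR. The classes partition: every interaction
  gets exactly one.

On-disk interval formats are BED (0-based half-open) and GTF (1-based
inclusive), converted at the boundary; within the package, alignment and
transcript coordinates are 0-based half-open throughout, and interval
set algebra (merge, intersection, containment) is delegated to
`GenomicRanges`/`IRanges`.

## The regulatory rule engine

Four independent, monotone filters annotate genome-projected
interactions; all are strand-aware and test containment against the
union of an interaction's genomic fragments:

1. **Splice-signal masking** (pre-mRNA, junction-spanning interactions):
   a splicing-factor CLIP interval entirely within the interaction
   region on the same strand. Spanned splice sites are classified
   *constitutive* iff every isoform of the gene whose span covers the
   boundary uses it, else *alternative* (single-isoform genes are
   vacuously constitutive).
2. **miRNA-site masking** (mRNA interactions): at least half of a merged
   CLIP-supported miRNA site — `ceiling(len/2)` bases, the conservative
   reading for odd lengths — inside the region. Site prediction itself
   (miRanda-style) is upstream; the package intersects the predicted and
   CLIP-supported sets (`intersect_site_sets`).
3. **SMD candidates** (mRNA interactions): an Alu element entirely
   inside the region *and* entirely inside the 3'UTR of a protein-coding
   target (3'UTR = everything 3' of the CDS end in transcript
   orientation).
4. **Editing overlap** (mRNA interactions): a single-base A-to-I editing
   site inside the region; half-open semantics, so a site at the
   exclusive end is outside.

Strandedness is enforced for all four filters. The source protocol
states it explicitly only for the splice filter, but strand-blind
matching would manufacture spurious antisense hits, so the package
applies it uniformly.

## Expression support

RPKM is computed from uniquely mapping reads only: reads at more than
ten mapping positions are discarded, reads touching more than one gene
are discarded, and the transcript-level count additionally requires
exactly one transcript (the gene-level variant relaxes only that last
condition, so the transcript-level expressed set is always a subset of
the gene-level set). Library totals are the unique-surviving read count
of the library at the chosen level — the denominator convention is this
package's documented choice. Mapping rows with more than one mismatch
are dropped with a warning, since the upstream mapper is expected to
have enforced the one-mismatch rule.

Two interaction-level criteria follow: *co-expression* (both partners
above the cutoff — default: any unique read — in at least one common
library) and *expression balance* in a library (less than 10-fold
difference, or the lncRNA in excess). The expression cutoff is
configurable because no universal value exists; ≥ 1 unique read is the
weakest defensible default.

## Validation harness

`specificity_test` pairs random pool members one-to-one (seeded,
without replacement) and reports the fraction with any
threshold-passing alignment; specificity is its complement under the
premise that random pairings do not interact. `sensitivity_test` scores
a user-supplied positive set. The curated positive pairs used in the
original study are not redistributable here, so the package ships a
constructor for synthetic positives with planted complements of known
score (`make_positive_pairs`); both harnesses accept any FASTA-derived
pairs. Raising the threshold can only lower both hit fractions, which
is tested as a monotonicity property.

## The synthetic fixture: what it emulates, and what it does not

`make_fixture` builds the desk-scale study conditions: two ~33-kb
chromosomes; twenty three-exon genes (exon widths 150/200/150, introns
600 and 700 nt, so each transcript has one intron that exceeds the
500-nt retention window and acquires an interior mask; mature length
500 nt with CDS at [120, 380) for coding genes; four genes non-coding;
alternating strands), one gene with a second exon-skipping isoform;
ten 800-nt single-exon lncRNA loci, one of them a natural antisense
transcript overlapping its target gene by 50 bp on the opposite strand
(the cis case, which also yields a perfect 50-bp antisense duplex of
composition-determined score). Six duplexes are planted as 40-column
perfect complements with fixed composition (25 G:C + 15 A:T, score
130 = 4·25 + 2·15 by the closed form): four in mature targets covering
the 3'UTR, CDS, CDS/UTR-straddle and non-coding region classes, one
spanning an exon–intron junction and one inside a retained intron
flank. Ten anti-pairing columns are written on each lncRNA flank of
every plant so that local extension past the planted window is
impossible in practice, making the truth coordinates exact. Regulatory
features are placed with known rule outcomes (one positive and one or
two boundary-negative cases per mechanism), and a three-library
read-mapping design fixes the co-expression and balance truth,
including an 11-position read, a two-isoform read and a two-gene read.

Background sequence is i.i.d. uniform. What the fixture therefore does
*not* emulate: realistic base composition and repeats (chance-hit rates
depend on composition — the calibration machinery exists precisely
because of that), isoform-rich gene models, sequencing error, and
biological positives that are partial, bulged duplexes rather than
perfect complements. Passing the fixture shows the machinery is exact
on known ground truth; it does not certify sensitivity on real,
imperfect duplexes.

Problem sizes used by the shipped tests and the acceptance script —
hundreds of ≤ 300-nt random pairs for the seeded-vs-exact equivalence,
200-pair nulls for calibration, the 21-transcript fixture for the
end-to-end runs — were chosen as the smallest scales at which every
property is non-trivially exercised.

## Known limitations

* Complementarity scoring ignores intramolecular structure and
  accessibility; scores are not hybridisation energies.
* The exhaustive extractor keeps full traceback matrices; it is meant
  for transcript-scale pairs (kilobases), not chromosome-scale inputs.
* The greedy non-overlap partition is tie-break-dependent (see above).
* Gumbel calibration assumes the null maxima follow extreme-value
  statistics; very short null sequences or extreme compositions can
  make the fit poor, and the degenerate-null error is the only guard.
* The rule engine treats supplied BED features as ground truth; it does
  not re-derive CLIP peaks, miRNA site predictions or repeat calls.
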