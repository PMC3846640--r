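---
title: "Transcript-guided scaffolding: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript-guided scaffolding: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txscaffold)
```

## The evidence model

A spliced transcript read aligned to a fragmented assembly is treated as a
chain of exons pinned to contigs. If the read's exons land on two contigs,
the read asserts that the contigs are adjacent on the chromosome and that
the sequence between them is the unassembled part of one intron. The
scaffolder's job is to accumulate such assertions across reads, arbitrate
between conflicting ones, and emit the consistent chains.

Three assumptions underlie this model:

* the contigs themselves are correct (no internal misassembly is detected
  or repaired);
* an aligned block order along a read reflects genomic order — violated by
  trans-splicing, gene fusions and paralogous alignments, which is why
  support arbitration and the intron cap exist;
* inter-contig gaps bridged by a read are intronic, which motivates
  estimating gap sizes from the intron-length distribution rather than
  from an insert-size model.

## Pipeline stages and their parameters

### Guide selection (MPI, MLC)

Percent identity is the web-BLAT *milliBad* formula in its mRNA-vs-DNA
form: with qAli and tAli the query and target spans, sizeDif =
max(qAli − tAli, 0) (target-side surplus is intronic, not penalised), and
total = matches + repMatches + mismatches,

$$\mathrm{milliBad} = \frac{1000\,(\mathrm{mismatches} + \mathrm{qNumInsert}
  + \mathrm{round}(3\ln(1+\mathrm{sizeDif})))}{\mathrm{total}}, \qquad
  \mathrm{identity} = 100 - \mathrm{milliBad}/10 .$$

Rounding is half-away-from-zero, the convention of the original
computation; R's banker's rounding would differ on exact halves. Length
coverage is (matches + repMatches + mismatches)/qSize — aligned bases, not
the span qEnd − qStart, so internal query gaps cannot inflate coverage.

Both thresholds are inclusive (≥), making the published operating points
attainable boundaries. Defaults: MPI = 90 (percent), MLC = 0.95
(fraction). Full coverage is judged on the best single alignment rather
than the union of alignments: a union rule would discard precisely the
split reads that carry linking information.

### Block building (bound)

Regions are sorted by read start (ties: longer first), strictly enclosed
regions removed (identical spans are kept and surface as ambiguous blocks),
and chained into blocks whenever consecutive end positions differ by less
than the clustering bound. The bound defaults to 10 bases: large enough to
absorb aligner end-jitter at exon boundaries, small enough that adjacent
exons (introns ≥ ~50 bp) never merge. Chaining on the last-added member
(single linkage in sort order) keeps the procedure deterministic and
order-stable. A block whose maximal length is tied between two regions is
evidence of a repeat or recently duplicated gene and is discarded whole.

### Connections and the intron cap (MIL)

For neighbouring blocks n (on contig A) and m (on contig B), the intron
between them is at least

$$D(n,m) = \mathrm{Length}(A) - \mathrm{End}(n) + \mathrm{Start}(m),$$

the tail of A past n plus the head of B before m, computed after mirroring
the coordinates of any minus-strand block (x → tSize − x) so that both
blocks are expressed in scaffold orientation. After that transform the
bound is provably non-negative; a negative value is treated as an internal
error, not clamped. Pairs with D(n,m) > MIL (default 100 kb, above which
true introns are rare) lose that read's support — a conservative filter,
since D is only a lower bound. A guide in which one contig reappears in a
non-adjacent block is discarded entirely as a likely repeat or chimera.

A connection and its mirror (seen from the antisense strand) are the same
physical join; the canonical form puts the byte-wise smaller contig id
first so both pool their supporting reads. One read contributes at most
one unit of support to a given connection.

### Graph resolution

Each contig, as a start, keeps only its maximum-support outgoing
connection; as an end, only its maximum-support incoming one. A tie in
either role disqualifies the contig in that role only. An edge survives
selection only when it is the choice of both of its endpoints
(mutual-best); one-sided bests are dropped. This is the only reading under
which every contig ends up in at most two connections and the walk from
predecessors through crossovers to terminators is well defined. Paths are
walked from predecessors in byte-wise contig-id order, which makes the
output independent of input record order.

Cycles (components with no predecessor) are unreachable by the walk; their
edges are discarded with a warning and their contigs remain as singletons —
silently losing contigs would break base conservation. If two selected
edges disagree about a shared contig's orientation, the path ends at that
contig and the downstream edges are discarded, again with a warning.

### Gap sizing

Intron lengths are strongly right-skewed, so the central tendency used is
the median — specifically the lower median, which is integer-valued and
reproducible — of all positive target-side inter-block gaps observed in the
*fully covered* reads (those are complete splice structures sitting inside
single contigs). When no such intron is observed the estimator falls back
to a configurable 1,000 bases with a warning.

At a junction with bound D below the median m, the gap receives
max(m − D, 1) Ns: the expected missing intron length after subtracting the
intronic sequence already inside the two contigs. When D ≥ m the bound
carries no size information beyond "a gap exists", and a conventional
100 Ns are inserted. When several reads support one junction the smallest
D is used — the most conservative estimate of missing sequence. The exact
N-count rule is a declared package choice (the quantity being estimated is
only ever known up to a bound) and is configurable through the median
passed to `write_scaffolds()`.

Scaffold FASTA is written at 60 columns; the AGP v2.0 layout uses
`scaffold`/`yes`/`align_trnscpt` gap metadata. Multi-contig scaffolds are
named `scaffold_<k>` in path order; singletons keep their input ids.

### Assessment

Against a trusted reference layout (contig spans, strands and ranks along
each reference sequence), each predicted join is classified:

* different reference sequences → **translocation**;
* relative orientation disagreeing with the reference strands →
  **inversion**;
* orientation agreeing and ranks adjacent in the implied direction →
  **consistent** (a join may legitimately walk leftwards when both contigs
  are flipped);
* otherwise a **relocation**, **correctable** when the reference distance
  between the contigs is below MIL (the skipped contigs are intronic and
  the join still recovers the full transcript), **errant** when not.
  Order-contradicting joins with agreeing orientation fall under the same
  distance rules — the taxonomy has no separate class for them.

The corrected accuracy rate is
1 − (inversions + errant relocations + translocations)/total, counting
consistent joins and correctable relocations as correct. Joins touching
contigs absent from the layout are reported separately as unevaluable and
excluded from the rate.

## The synthetic-data generator

The generator emulates the situation the scaffolder is designed for, at a
size where exhaustive checking is cheap. Defaults, chosen once as the
package's study conditions:

| parameter | default | rationale |
|---|---|---|
| genes | 100 on 1 chromosome (~1 Mb) | enough junctions for stable counts, seconds to run |
| exons per gene | 3–8, 80–400 bp | typical compact vertebrate gene structure |
| intron lengths | log-normal(meanlog 7, sdlog 1), floor 50 bp | right-skewed, median ≈ 1.1 kb, occasional multi-kb outliers |
| intergenic gaps | 500–2,000 bp | separates gene neighbourhoods without dominating the genome |
| contig breaks | each intron broken with p = 0.5; every intergenic gap broken; exons intact | produces both guide reads (broken introns) and fully covered reads (intact genes) — the latter are the intron-median estimators, as in real data |
| read errors | 0 (substitution-only when enabled) | substitutions shift identity without perturbing PSL block structure |
| antisense rate | 0.5 | strand of ESTs/mRNAs is unknown in practice; exercises the canonical pooling |
| poly(A)-like tail | 5–30 bp, unaligned | keeps length coverage just below 1, so MLC acts as a real boundary rather than a degenerate one |
| isoform / fusion rates | 0 (available as confounders) | skipped exons model alternative splicing; fusions model chimeric reads that create false joins |

Truth PSL records are constructed from the generative coordinates, not
from an aligner, with match/mismatch counts obtained by direct sequence
comparison — so substitution-bearing reads also receive exact records.

What the generator does **not** model, and what passing tests therefore do
not show about real data: expression-level variation and read depth (every
gene contributes exactly one read), indels and alignment ambiguity from an
actual aligner, repeat families producing high-identity secondary
alignments, polymorphism between the transcript source and the assembly,
and reference layouts with minus-strand or missing contigs (exercised in
unit tests but not generated). The block-clustering stage in particular
sees only clean, jitter-free region boundaries here.

## Numerical choices and degenerate inputs

* Inclusive (≥) thresholds throughout; exact-equality ties in block length.
* Lower median for even counts; all gap arithmetic in integers.
* Alignments with zero aligned bases get identity 0 with a warning rather
  than an error, so one corrupt record cannot stop a run.
* An empty PSL, or one whose reads are all fully covered, yields output
  FASTA identical to the input contigs.
* Contig-id comparisons (canonical keys, walk order) are byte-wise
  (C-locale radix), so results do not depend on the session locale.
* `set.seed` offsets (+0 genome, +1 fragmentation, +2 reads) keep the four
  generator stages independently reproducible under one seed.

## Known limitations

* Role selection operates on canonical directed edges. In a chain whose
  contig ids are not monotone along the chromosome, a middle contig can be
  the canonical *start* of both of its joins; the per-role maximum then
  keeps only one. This forgoes a join (contiguity loss), never invents one
  (no accuracy loss). A two-sided, contig-end-based selection would lift
  this at the cost of departing from the per-role maximum rule implemented
  here.
* Identity and coverage are judged per alignment, not per read-best
  alignment; a read with several weak alignments of one region can pass
  MPI in all of them and is arbitrated only later, at support selection.
* Gap N-counts are estimates from a lower bound and a median; they are
  placeholders for downstream gap filling, not measurements.
* The assessor trusts the reference layout completely; misjoins in the
  reference itself surface as false misjoin calls against the prediction.

## Problem sizes used by the test suite

Unit tests run on hand-built records and 8–40-gene simulations; the
recovery check runs the full 100-gene study; the resolver is compared
against a brute-force oracle on an exhaustive enumeration of small
connection graphs (all 2-node graphs with weights ≤ 5, all 3-node graphs
with weights ≤ 3, ~4,000 structured cases) plus 2,000 random graphs of up
to 8 fragments with weights ≤ 5; conservation and N50 monotonicity are
checked across 20 seeded 30-gene runs. These sizes were chosen so the
whole suite completes in a few minutes while every code path, including
cycle and tie handling, is exercised.
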