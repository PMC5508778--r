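---
title: "Hi-C scaffolding: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hi-C scaffolding: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicscaff)
```

## The problem

Long-read assemblers produce contigs of hundreds of kilobases to a few
megabases, far short of chromosome arms. Hi-C proximity ligation captures
pairs of loci that are close in the nucleus; because chromosomes occupy
territories, two loci on the same chromosome interact far more often than
loci on different chromosomes, and the interaction probability decays
rapidly with genomic distance. A read pair whose two mates land on two
different contigs is therefore evidence that those contigs are near each
other on a chromosome — enough, in aggregate, to order and orient contigs
into chromosome-scale scaffolds without knowing the chromosome number in
advance.

`hicscaff` implements this scaffolding strategy as four stages: alignment
filtering, misassembly correction, scaffold-graph construction, and
path-based layout with small-contig insertion.

## Alignment filtering

Only read pairs with *both* mates mapped are informative, and only
confidently placed ones: pairs are kept when both mates have mapping
quality above a threshold (default 30). Multi-mapping reads carry MAPQ 0
under BWA-style scoring and are removed by the same filter; secondary and
supplementary records are ignored outright. A pair with one confident and
one ambiguous mate is dropped whole — its linkage evidence is only as good
as its worse mate. Coordinate-duplicate pairs are kept by default (PCR
duplicates are a library property, not an alignment one); `dedup = TRUE`
collapses them.

Internally all coordinates are 0-based half-open; SAM input is converted
on read, which confines the off-by-one surface to one parser.

## Misassembly detection

For a read pair mapped within one contig, the *physical coverage*
interval is everything from the leftmost mapped base of either mate to
the rightmost — reads plus the gap between them. Per-base physical
coverage counts the pairs spanning each base. Across a genuine join the
spanning pairs are plentiful; across a chimeric join of two unrelated
sequences, none exist (a mate that "should" fall on the far side maps to
a different contig instead), so per-base physical coverage dips sharply.

The detector finds the contiguous interval minimising
$\sum_i (c_i - \delta)$, the deepest deficit against an expected level
$\delta$ — the minimum-sum-subarray variant of Kadane's algorithm,
computed in one vectorised pass over prefix sums. Choices that matter:

* **$\delta$** defaults to half the median of the contig's *nonzero*
  per-base physical coverage. A per-contig robust statistic adapts to
  uneven sequencing depth; the nonzero restriction keeps long zero runs
  from dragging the estimate down.
* **Deficit threshold.** A call must carry a deficit of at least
  $\delta \times$ `min_equiv_span` (default 5000), i.e. the equivalent of
  5 kb of entirely missing coverage. Expressing the threshold as an
  equivalent span makes it depth-independent.
* **Edge margin.** Physical coverage necessarily ramps to zero at contig
  ends — no pair can span past the sequence — so intervals whose midpoint
  lies within `edge_margin` (default 10 kb) of a segment end are never
  called.
* **Iteration.** The scan returns one interval; after an accepted call
  the contig is split at the interval midpoint and both halves are
  re-scanned (with $\delta$ re-estimated) until nothing further passes.
  The midpoint is as good a point estimate of the junction as any: the
  deficit is approximately symmetric about it.

Contigs split into `<name>_1`, `<name>_2` (recursively), total bases are
conserved, and the pair table is remapped onto the pieces. The stage can
be disabled (`break_detection = FALSE`) when contigs were already
corrected by other means, e.g. optical maps.

## Link scoring and the scaffold graph

Each contig contributes two nodes, `B` (beginning) and `E` (end). Only
pairs mapped within a window of length $l$ at a contig end count as
linkage; the effective window is $\min(l, \lfloor L/2 \rfloor)$ so the
two windows of a short contig never overlap. The four tag combinations
BB/BE/EB/EE encode the relative orientation of the joined contigs.

Raw link counts are length-biased, so edges are weighted as

$$W = \frac{\mathrm{links}(C_1, C_2)}{RE(C_1) + RE(C_2)}$$

where $RE(C)$ counts restriction-enzyme recognition sites in the end
window (IUPAC-aware; the reverse complement is also scanned for
non-palindromic motifs), plus a pseudocount of 1 per window that keeps
the denominator positive. Expected Hi-C pair yield scales with cut
sites, not bases, so this cancels the dominant bias. Without sequences
or an enzyme, raw-count mode ($W = $ raw links) is available explicitly.

Graph construction is greedy: candidates below `min_links` raw pairs
(default 5) are discarded as noise, survivors are sorted by weight
descending (ties: raw links descending, then edge name, for
deterministic output), and an edge is added only when *neither* endpoint
is already in the graph — a maximal-weight matching on end nodes. CONTIG
edges then join B and E of every linked contig. Two facts follow: no
node exceeds degree 2, and (after cycle removal) every component is a
simple path with exactly two degree-1 ends. The classic cycle is the
4-cycle from selecting both `X:B–Y:B` and `X:E–Y:E`; any cycle that
appears is opened by deleting its minimum-weight Hi-C edge (CONTIG edges
are never deleted). Cycles longer than 4 can arise when a whole
component closes on itself, so the removal iterates over every cyclic
component rather than special-casing length 4.

**Defaults.** $l$ = 500 kb, matching the range over which Hi-C signal is
appreciably above background; `min_links` = 5 raw pairs. Both are
tunable, and real datasets may need tuning — link density varies by
orders of magnitude between libraries.

## Layout and small-contig insertion

Each component's unique path is traversed from its terminal with the
lexicographically smaller contig name (so output is deterministic and
unchanged by the reversal symmetry of a scaffold). Crossing a CONTIG
edge B→E places the contig forward; E→B, reverse. Components with more
than `n_th` contigs (default 3) are *seed scaffolds*; smaller ones, and
contigs with no surviving edge, are small scaffolds.

Residual length bias can exclude small contigs from the matching, so
each contig of each small scaffold is then assigned to the seed with the
greatest total weight to it in the *original* (pre-filter, pre-matching)
candidate edge set, and tried at every gap of that seed in both
orientations. The score of a hypothetical insertion is the total
adjacent-pair weight of the resulting layout — the seed's internal
weights, minus the adjacency an interior insertion splits, plus the at
most two new adjacencies. The argmax slot wins; ties go to the smallest
position, then forward orientation. Contigs are inserted in descending
order of assignment weight against the growing seed (sequential greedy,
not joint optimisation). A small scaffold none of whose contigs is
assignable passes through intact; individually unassignable contigs
become singletons. The contig multiset is always conserved.

## Output conventions

Scaffold FASTA joins oriented contig sequences with runs of 500 `N`
(gap length tunable); AGP v2.1 describes the identical structure (gap
type `scaffold`, linkage `yes`, evidence `proximity_ligation`), so
either artifact reconstructs the other exactly — the test suite asserts
byte-identity. Scaffolds are named `scaffold_<k>` by decreasing length.
Break calls export as BED, the graph as TSV/DOT, the layout as TSV, and
the run configuration is echoed as JSON. The pipeline draws no random
numbers, so identical inputs give byte-identical outputs.

## The simulator: what it emulates, and what it does not

Every stage is testable without external data via a seeded simulator:

* uniform-random chromosomes (default 4 × 2 Mb) — restriction sites for
  a 4-cutter such as GATC then occur every ~256 bp on their own;
* fragmentation into contigs with lengths uniform on [50, 200] kb
  (~60 contigs), each reverse-complemented with probability 1/2 and
  renamed in shuffled order, with full truth tables;
* optional chimeras: a configurable fraction of fragments is fused
  pairwise across chromosomes, junction recorded;
* Hi-C pairs (default 200,000): inter-chromosomal with probability
  `p_inter` (default 0.05), otherwise a uniform locus and a mate at a
  signed exponential distance (scale 15 kb, reflected at chromosome
  ends), both mapped through the fragmentation truth into perfect
  MAPQ-60 contig alignments.

The exponential decay scale of 15 kb reflects that most cis-contact mass
in real libraries sits at short range; it also determines the width of
the coverage ramp at contig ends, which the 10 kb edge margin of the
break detector must accommodate. The defaults above are the package's
reference study conditions: large enough that each chromosome yields a
well-populated path, small enough that the whole suite runs in tens of
seconds.

The simulator deliberately omits fragment-length, GC and mappability
biases, TAD structure, translocation-scale structural noise, and
alignment error (reads are emitted as perfect alignments). Passing tests
therefore demonstrate correctness of the algorithms under the stated
contact model, not performance on any real library; on real data the
MAPQ filter, `min_links`, and $l$ carry the burden the simulator skips.

## Known limitations

* One scaffolding round; no iterative re-scaffolding or joint re-scoring
  of seeds after insertion.
* Orientation evidence is end-window counting only; assembly-graph
  topology is not consulted.
* Misassembly detection needs a coverage drop: collapsed repeats without
  one are invisible to it.
* Parameter defaults suit the reference conditions; real libraries
  require tuning `l` and `min_links`.

## Reference problem sizes

The packaged checks run the full pipeline on the reference conditions
(4 × 2 Mb, ~60 contigs, 200,000 pairs; a chimeric variant at
chimera rate 0.1), 200 random candidate sets for the graph laws, 500
random profiles against an exhaustive minimum-sum-subarray oracle, and
30 randomized insertion problems against a brute-force scorer.
`scripts/acceptance.R` re-runs the same computations from scratch under
a caller-supplied seed.
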