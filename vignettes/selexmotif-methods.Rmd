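---
title: "Methods: HT-SELEX motif discovery with selexmotif"
author: "selexmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HT-SELEX motif discovery with selexmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In an HT-SELEX experiment, a DNA-binding protein (typically an isolated
DNA-binding domain, DBD) is mixed with a library of double-stranded
ligands, each carrying a randomized region of 20 or 40 bp framed by a 6 bp
5' barcode and a 2-3 bp 3' barcode.  Bound ligands are recovered, PCR
amplified, and used as the input of the next cycle; sequencing after each
cycle yields per-cycle read sets in which sequences preferred by the
protein are exponentially enriched.  `selexmotif` turns those read sets
into binding models: a seed subsequence, a position weight matrix (PWM)
around it, the pairwise base dependencies within the site, and comparison
structures (similarity matrices, dendrograms, networks) across many
experiments.

## Gapped patterns and the Huddinge distance

The unit of counting is the *gapped pattern*: a string over `A,C,G,T,n`
where `n` is an undefined position.  Canonical patterns have defined
bases at both ends and (in the counting space) a single internal run of
`n`; this captures both contiguous motifs and dimeric half-sites with a
variable spacer.  Two patterns are compared with the Huddinge distance

> d(P, Q) = d − a,

where `d` is the larger number of defined bases in either pattern and
`a` is the maximum number of positions with equal defined bases over all
rigid relative offsets (no re-gapping during alignment).  The distance
is 0 exactly for identical canonical patterns (up to strand when strand
merging is on), and distance-1 neighbours fall into interpretable
classes: substitutions, one-base-shorter or -longer patterns, shifts and
gap-length changes.  Because SELEX ligands are double stranded, counting
merges a pattern with its reverse complement by default, and the metric
then takes the minimum over strands so that metric and count space agree.

A subtlety worth noting: a *shift* of a gapped pattern can never be at
distance 1, because the gap forces the two defined-base structures out of
register; `shift_min_distance()` quantifies this (2 for `ACnGT`).  For
ungapped patterns the same quantity is 1.

## Seed discovery (local maxima)

`count_patterns()` tallies every in-bounds pattern; by default a read
contributes at most once per pattern (`per_read`), which damps PCR
jackpots, while `per_occurrence` mode retains the containment
monotonicity property used by the test oracles.  `find_local_maxima()`
reports patterns enriched above their whole Huddinge-1 neighbourhood:

* strictly higher counts than every equal-length neighbour;
* against a neighbour with one fewer defined base, the count must exceed
  `theta` times the neighbour's count — a shorter pattern contained in a
  longer one is always at least as frequent, so the raw comparison must
  be discounted;
* a neighbour with one more defined base wins when its count exceeds
  `theta` times the pattern's count;
* a floor of `min_count` occurrences suppresses sampling noise.

`theta` defaults to 0.5: under a null of no enrichment the expected
long/short count ratio is about 1/4 per added defined base, under
perfect enrichment it approaches 1, and 0.5 is the midpoint on the log
scale.  It is exposed as a parameter because the choice is a genuine
trade-off between sensitivity to long motifs and noise.  Ties between
equal-length neighbours break dominance (strict inequality), making the
output deterministic together with the count-then-lexicographic sort.

`find_local_maxima()` scans the whole table by default, which is what
the exhaustive-oracle tests check.  For the "top seeds of a large
experiment" question a `max_candidates` limit evaluates only the
highest-count patterns (neighbour counts still come from the full
table); the top of the ranking is unchanged whenever at least one
candidate passes.  The rank-1 maximum becomes the primary model;
further maxima are classified against it as `spacing_orientation`
(same defined bases or half-sites, different spacer or orientation),
`flank` (end extensions), `dinucleotide` (exactly two adjacent differing
positions in the best alignment), or `unrelated`, with precedence in
that order — the most specific structural change is tested first.
Expert seed refinement is deliberately out of scope; an explicit
`seed =` argument bypasses discovery instead.

## Multinomial PWMs and background correction

`multinomial_matrix()` aligns each read to the seed at its best-matching
window (fewest mismatches over defined seed positions, ties to the
leftmost placement and then the forward strand; the window of width
`span + 2*flank` must lie fully inside the read, so sites hanging off
the read edge are excluded rather than padded).  "Multinomial order n"
is formalized as: a window contributes to the count cell (base, column)
when it mismatches the seed at *other* defined positions in at most
`n − 1` places.  Order 1 therefore counts exact matches everywhere plus
single-mismatch windows at the mismatched column only, which is what
makes the per-column base distributions estimable without an iterative
model fit.  Cell counts are non-decreasing in the order.

Background correction divides each observed cell by the expectation
obtained by applying the *same* counting rule to the unselected cycle-0
reads (scaled to equal totals), then renormalizes columns.  A
pseudocount (default 1) is applied symmetrically to observed and
background cells, so an observed matrix identical to its background
corrects exactly to the uniform matrix and empty background cells never
divide by zero.  Subtractive correction (`method = "subtract"`) is
available; division is the default because enrichment in SELEX is
multiplicative across cycles.  `classify_site_structure()` is a
deliberately simple heuristic — slide the PWM's most informative
subregion against the full matrix on both strands and count
non-overlapping high-correlation placements (1 = monomer, 2 = dimer,
3 = trimer, 4 = dimer of dimers); it classifies clean repeats and is not
a substitute for inspecting the logo.

## Dinucleotide dependencies

For every position pair of the seed window, `dependency_table()`
compares the observed joint base-pair distribution with the prediction
of a mononucleotide model (the product of the joint's marginals).  The
score is the fraction of counts mispredicted — the total variation
distance `0.5 * sum |joint − product|` — scaled by 200 so that 0% means
independence and 100% means half of all counts are mispredicted (the
equal AA/TT case).  This formalization reproduces both anchor cases
exactly.  It is not clipped by default: a fully coupled 4-state diagonal
joint reaches 150%, and silently capping it would hide genuine structure
(a `clip` argument caps at 100 for display).  Pairs involving gap and
flank positions are included — those are exactly the positions where a
dependency can be seen at all when sites are selected by exact seed
match, since conditioning on the seed's defined bases fixes them.

## Motif and domain similarity

Motifs of different widths are compared on a common axis: every gapped
6-mer (3 defined bases, a middle gap of 0-10, 3 defined bases) is scored
against each PWM as the maximum over rigid placements and both strands of
the summed log frequencies (pseudocount 0.01 avoids log 0; gap variants
that do not fit score a flat background value).  Motif similarity is the
Pearson correlation of two such score vectors; taking the per-pattern
maximum over strands makes the similarity exactly invariant to
reverse-complementing either motif.  The gap range and k are
configurable; Spearman correlation is available where outlier k-mers
dominate.  Externally computed similarity matrices (e.g. SSTAT-style
scores) can be loaded from TSV and used in all downstream outputs.

Protein-domain similarity is a local alignment (BLOSUM62, gap open 11 /
extend 1, blastp-like defaults) with the score multiplied by the
alignment length and divided by the length of the shorter sequence —
long, confident alignments score higher than short spurious ones at
equal bit score.  Multi-domain proteins are handled either by the best
domain pair (`max_domain`) or by concatenation.  Clustering uses the
euclidean distance between similarity-matrix rows with average linkage
(`stats::hclust`), serialized as Newick via `ape`.

## Visualization

The barcode logo encodes each position as four bars (A, C, G, T left to
right): bar width is the base frequency (0-1); the height and colour
intensity of all bars at a position equal the frequency of the most
common base there.  That frequency lives in [0.25, 1] and is mapped
*identically* (a uniform column has height fraction 0.25, not 0) —
"proportional" is taken literally, which keeps uninformative positions
visible but faint and makes columns comparable across motifs.  Base
colours are A green, C blue, G orange, T red.  Sequence logos use the
conventional information-content scaling (letter height = frequency ×
column bits, at most 2 bits).  The dependency heatmap colours
position-pair tiles by score with a 4×4 dot grid marking over- (yellow)
and under- (blue) represented base pairs; the 2D similarity heatmap
encodes amino-acid similarity in the red channel and motif similarity in
the green channel, so pairs similar in both render yellow.  All
renderers are pure functions emitting byte-identical SVG, which the
tests exploit by parsing the geometry back.

## The synthetic SELEX generator

`simulate_experiment()` emulates the study design: uniform random
initial libraries of the design's randomized-region length (20 bp
default, 40 bp supported), 3 cycles of selection at 50,000 reads per
cycle by default, selection strength 5.  Affinity is winner-take-all:
the maximum over placements, strands and mixture components of the
site's probability ratio against the uniform background — single-site
binding dominates for short ligands (a sum-occupancy mode was considered
and rejected as second-order at these lengths).  Retention probability
is proportional to `1 + strength × affinity`, and retained reads are
resampled with replacement to the target depth, which reproduces PCR
duplicates on purpose so that `per_read` counting has something to
correct.  Components plant a PWM, a PWM with one dinucleotide-coupled
position pair (a joint 4×4 table replacing the product of marginals), or
a gapped consensus with spacing/orientation variants.  Everything is
reproducible from a single integer seed.

What the generator does *not* emulate: sequencing errors, barcode
cross-talk, carrier effects, position-dependent ligand accessibility,
and non-specific binding.  Passing the recovery tests therefore shows
that the estimators are correct under the stated sampling model, not
that real libraries are free of those artefacts.

## Numerical and design choices

* Strand-canonical form: the lexicographically smaller of pattern and
  reverse complement under `A < C < G < T < n`.
* Barcode demultiplexing is exact-match; reads with `N` in the
  randomized region are dropped (the downstream pattern space is
  4-letter).  Both choices are policies of this package, stated as such.
* Pattern-space bounds default to 4-8 defined bases with a single middle
  gap; they are fully configurable and the desk-scale analyses in the
  tests use 5-7 defined bases with gaps up to 2.
* Degenerate inputs fail loudly: all-`n` patterns, empty site sets,
  zero-variance score vectors, NA similarity matrices.
* PWM columns whose corrected counts are all zero renormalize to the
  uniform column rather than NaN.

## Problem sizes used by the test-suite

The automated checks run at desk scale, chosen so the whole suite
completes on a single CPU while keeping every statistical margin wide:
exhaustive Huddinge-oracle agreement over all pattern pairs with up to 3
defined bases (gap ≤ 2) plus 600 random pairs up to 6 defined bases;
20 replicate seed-recovery simulations at 10,000 reads × 3 cycles;
PWM-recovery at 50,000 reads; dependency detection at 6,000-8,000 reads.
The headline dataset-scale numbers of a full HT-SELEX compendium
(hundreds of TFs, curated seeds) require the original archived reads and
expert curation and are out of scope here.

## Known limitations

* The local-maxima scan is exact but exhaustive; at bounds much beyond
  8 defined bases the pattern space grows as `4^d`, and `max_candidates`
  becomes the practical mode.
* `classify_site_structure()` and `classify_model_relation()` are
  structural heuristics; borderline cases fall through to
  `monomer`/`unrelated` rather than guessing.
* The similarity of very wide motifs is dominated by their best 6-mer
  window; increase `k` for long dimeric sites.
* The simulator's selection model is monotone in affinity; it cannot
  produce the non-monotone cycle artefacts occasionally seen in real
  experiments (e.g. primer-dimer takeover).
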