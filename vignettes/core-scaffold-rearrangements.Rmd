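---
title: "Core-genome scaffold comparison and repeat-mediated rearrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-genome scaffold comparison and repeat-mediated rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panrearr)
```

## The problem

Closely related bacterial strains share most of their chromosome as a
*core genome*: sequence blocks present in every strain of the sample.
Writing each strain's core blocks in chromosomal order, with a sign for
strand, turns every strain into a *core-genome scaffold* — a signed
permutation — and strain-to-strain structural differences into classical
genome-rearrangement arithmetic. This package implements that analysis
end to end: scaffold construction from a whole-genome-alignment block
map, grouping of identical scaffolds, elimination of "independent"
non-inversion events, exact minimum-inversion distances and scenarios,
and a sequence-level test of the hypothesis that drives the analysis:
long inversions are bounded by a pair of inverted repeats (IRs, typically
IS elements), and transposition-like events by direct repeats (DRs), so
that the sequence at the ends of the rearranged segments is conserved.

## Scaffolds from block maps

A block map is a table of block occurrences (`strain`, `block`,
`contig`, `start`, `end`, `strand`; 0-based half-open coordinates),
either supplied directly or derived from a Mugsy-style MAF alignment
(`blocks_from_maf()`). Blocks present in all strains are core; in a
strict subset, dispensable; in one strain, strain-specific. Only core
blocks enter scaffolds. Two filters reduce noise:

* `filter_short_blocks()` removes core blocks shorter than `min_len`
  (default **500 bp**, measured in one designated reference strain since
  per-strain lengths differ slightly; a block of exactly 500 bp is
  kept).
* `merge_core_blocks()` iteratively fuses two core blocks that are
  genomically adjacent *in every strain* with consistent relative
  orientation (`a,b` both forward, or `b,a` both reverse). Adjacency is
  judged among core blocks only, so interleaved dispensable sequence
  does not break a fusion. Merging drastically shrinks scaffolds
  without losing rearrangement signal, because a junction conserved in
  all strains can never be a breakpoint of any pairwise comparison.

Scaffolds are single-chromosome by assumption (bacterial); multi-contig
strains are rejected rather than silently concatenated. Identical
signed sequences are grouped (`build_groups()`), numbered by decreasing
group size so group 1 is the largest, ties by order of first appearance.

## Rearrangement arithmetic

All comparisons relabel the pair so the target becomes the identity
`+1 +2 ... +n`. Two permutations first pass through
`collapse_common_adjacencies()`, which fuses runs of blocks adjacent in
both with consistent orientation. Fusion is *maximal* (run-based, left
to right): any pair adjacent in both genomes merges, including pairs a
worked illustration might leave unmerged; the grouping record maps every
merged block back to its run of original labels so event and scenario
endpoints can be reported in the input labelling.

**Independent events.** Four restricted event forms are detected on the
collapsed pair, using sentinels `+0` and `+(n+1)` so events at scaffold
ends are visible. Writing a window as signed-consecutive when each
entry is its left neighbour plus one (which covers the ascending
positive pattern and its descending negative mirror at once):

* *independent transposition* — adjacent pair whose swap makes a window
  of four signed-consecutive; removes exactly 3 breakpoints (its 6-edge
  breakpoint-graph cycle resolves into three trivial cycles);
* *independent inverted transposition* — adjacent pair with one sign
  flipped; 3 breakpoints;
* *independent block interchange* — two separated single blocks whose
  swap makes both flanking triples signed-consecutive; removes exactly
  4 breakpoints (two interleaving 4-edge cycles resolve);
* *independent inverted block interchange* — as above with both signs
  flipped; 4 breakpoints.

`eliminate_independent_events()` loops: collapse, scan in the fixed
priority order above (leftmost match first), apply, re-collapse. The
breakpoint deltas (3/3/4/4) are asserted at every application, and
breakpoints strictly decrease, so termination is guaranteed. The scan
order is a convention — the event *counts* per kind are what the
analysis uses; when overlapping patterns compete, the priority rule
decides deterministically.

**Inversion distance.** `inversion_distance()` is exact: on the capped
doubled breakpoint graph, distance = `(n+1) − cycles + hurdles +
fortress`. Hurdles are counted among unoriented components of the
cycle-interleaving graph (minimal components, plus a greatest component
containing all others); a fortress is declared when the hurdle count is
odd and every hurdle is a superhurdle (removing it does not lower the
hurdle count). The implementation contract is equality with
`bfs_oracle()`, a breadth-first search over the full space of signed
permutations, feasible to n = 8: the test suite checks all 4,282 signed
permutations with n ≤ 5 and 500 random cases each at n = 6 and 7.
Fortresses cannot occur at oracle-checkable sizes, so that branch is
covered by construction-level tests only — a known limitation, though
fortress permutations are vanishingly rare at the scaffold sizes this
analysis meets.

**Scenarios.** `optimal_scenario()` rebuilds one optimal scenario
greedily: at each step, among all inversions that reduce the exact
distance by one (at least one always exists when the distance is
correct), the one with the smallest left then smallest right position is
applied. This makes scenarios deterministic and testable; the specific
optimal scenario is generally not unique, so only validity (reaches the
target) and length (equals the distance) are contractual.

**Duplicated blocks.** Repeat-borne extra copies of a block make a
scaffold a non-permutation. `dedup_duplicates()` keeps, per duplicated
block, the copy sharing the most orientation-aware adjacencies with a
duplicate-free reference scaffold (ties: first occurrence). This is a
stated convention; the underlying data do not determine the choice, and
the retained copy is exactly the "copy next to its reference neighbour"
in the cases that motivated the rule.

**Closest pairs.** For each group, `closest_pairs()` compares against
every other group (dedup, eliminate, distance) and selects the target
with the smallest *total* rearrangement distance `inv_d + r_d`, ties to
the lower group id (the larger group). Ranking by `inv_d` alone is
tempting but wrong: two scaffolds that differ by overlapping inversions
can legitimately reduce to a single independent inverted transposition
(`inv_d` 0, `r_d` 1) — with a pure `inv_d` ranking such incidental pairs
displace the biologically closer group, and the resulting tables no
longer reflect the inversion events the analysis means to expose.

## Repeats at breakpoints

For each inversion of a closest pair, windows are cut around the two
breakpoints of the inverted segment: from the end of the preceding core
block minus `margin` to the start of the first inverted block plus
`margin` (and symmetrically on the right), clipped to the genome and
capped. Defaults: `margin` 2,000 bp, `cap` 20,000 bp, minimum repeat
length 50 bp, minimum identity 0.90, seed length 15, long-inversion
threshold 10,000 bp. Only the long-inversion threshold comes from the
underlying study; the others are conventions chosen for IS-scale repeats
(0.7–1.5 kb) and must remain configurable because the study reports no
detection parameters. A repeat copy must intersect its window to count
as flanking.

Detection (`find_inverted_repeat()`, `find_direct_repeat()`) is
seed-and-extend: exact k-mer seeds between the left window and the
(reverse-complemented, for IRs) right window, one gapless X-drop
extension per diagonal (match +1, mismatch −2, drop 25), keeping the
best hit meeting the length and identity floors. Gapless extension is a
deliberate simplification: the simulator plants substitution noise only,
and at IS-element scale indel-free copies dominate in real data too;
repeats diverged by indels will be reported shorter or missed.
`locate_repeat_occurrences()` reuses the same machinery against whole
genomes on both strands; `check_event_ends()` applies it across the 3
(transposition kinds) or 4 (interchange kinds) junction windows of a
multi-break event. Detected repeats are labelled `A`, `B`, ... by
greedy clustering at 90% identity in discovery order, and each flanked
inversion carries a presence code: 0 = repeat found in source-group
strains only, 1 = closest-group only, 2 = both.

## The synthetic world

`default_dataset(seed = 0)` is the package's reference world, used by
the end-to-end tests: 5 strains from a ~200 kb ancestor of 40 core
blocks. Block lengths are lognormal (median 4 kb, sd-log 0.45, clipped
to 0.5–80 kb, matching the observed core-block length range), spacers
50–400 bp, GC 0.55 (between the two studied species), IS-like repeats
700–1,500 bp. Strain 1 is the unrearranged ancestor; strains 2–4 carry
five IR-mediated inversions (each > 10 kb, each bounded by its own
planted IR pair); strain 5 carries one DR-mediated transposition at a
three-copy direct repeat. Substitution noise is off by default; a
per-strain rate of 0.001 is the convention used to exercise approximate
repeat matching, mimicking the slight between-strain repeat divergence
seen in real strains.

Genomes are linear segment tracks (block / spacer / repeat segments), so
the central mechanism is true *by construction* and asserted literally
at every event application: an IR inversion reverse-complements strictly
the segment between the two mediating copies, a DR transposition swaps
the two inter-copy segments, and in both cases the emitted sequence
outside the outermost mediating copies is bitwise identical before and
after. The truth log records each event's mediating repeat, outer
extent, and block-level effect, and the replay of block-level effects
reproduces each strain's scaffold.

What the generator does *not* emulate — and hence what a green test does
not establish: dispensable and strain-specific sequence content beyond
neutral spacers, indels and gene gain/loss, circular chromosomes and
origin-shifted rotations, multi-copy IS families scattered outside
event junctions, and phylogenetically structured multi-generation event
histories. Pipeline recovery on this world demonstrates internal
consistency of scaffold building, elimination, distance and flank
detection, not aligner behaviour on real genomes.

Two larger fixtures, `synthetic_scaffold_table("paeruginosa")` and
`synthetic_scaffold_table("ecoli")`, stand in for the per-strain
scaffold tables of the 25 *P. aeruginosa* and 31 *E. coli* complete
genomes, whose originals live in an external supplementary spreadsheet
that is not redistributed with the package. They are generated by an
explicit rearrangement script against reference scaffolds of 69 and 49
merged blocks and reproduce the published group structure (8 and 9
scaffold groups, sizes 13+6 and 21+3), the published closest-pair rows
(e.g. group 6 → group 5 at inversion distance 7 with three independent
events; group 8 → group 1 at distance 0 after four independent events;
the *E. coli* inverted block interchange between groups 6 and 1 and
inverted transposition between groups 9 and 1), and the totals of 13 and
17 inversions over distinct closest pairs. Tests against them are
construction-consistency checks of the pipeline at realistic scale, not
reproductions from the real tables.

## Numerical and degenerate-input choices

* Permutation positions are 1-based; genomic coordinates are 0-based
  half-open (BED convention in files; the human-readable report labels
  both).
* The RNG stage seeds of the simulator are drawn from a seeded
  `sample.int` stream rather than computed as `seed + k`: adjacent
  Mersenne–Twister seeds in R produce heavily correlated uniform
  streams, enough to plant a phantom ~97%-identical copy of a "random"
  repeat inside unrelated sequence.
* `bfs_oracle()` refuses n > 8 (resource guard). Its per-n distance
  table is cached per session, so exhaustive checks amortise to
  lookups.
* Empty windows, inversion-free pairs, single-block permutations,
  margin-0 windows and zero-length interiors all degrade to empty
  results rather than errors; genuinely invalid input (mismatched block
  sets, duplicated blocks where permutations are required, multi-contig
  strains, colliding repeat placements, wrong junction counts) errors
  loudly.

## Known limitations

Linear, single-chromosome, unichromosomal permutations only — no
translocation, fission/fusion, or circular rotation equivalence; no
weighted-operation or DCJ distances; general (non-independent)
transpositions are not inferred, only the restricted independent forms;
repeat detection is gapless and reports no protein-level annotation of
the repeats. The 533-block core genome, the 185→69 merge and the real
8/9 group structure of the two species require the original NCBI genomes
plus a whole-genome alignment run and are documented as
not desk-reproducible; the pipeline accepts such data through
`blocks_from_maf()` or a block-map TSV when available.
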