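---
title: "Comparative feature analysis of syntenic lncRNA loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative feature analysis of syntenic lncRNA loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncortho)
```

# The problem

Some long non-coding RNAs keep their function while losing almost all
primary-sequence similarity between species. The NEAT1/MALAT1 pair is the
canonical example: two syntenic genes on one strand of one chromosome, both
matured by the tRNA-processing machinery (a 3'-end triple helix stabilizes
the transcript after a tRNA-like element is cleaved off), yet MALAT1 is
conserved at the sequence level across vertebrates while NEAT1 orthologs can
share barely 20% identity between mammalian orders. For such genes, ortholog
identification cannot rely on whole-gene homology; it has to anchor on the
few elements that *are* conserved — the syntenic conserved partner, the
TATA-box promoter, and the 3'-end triple-helix/tRNA-like block — and the
comparative analysis has to characterize features that survive without
alignment: repeats, transposable elements (TEs), self-complementary regions,
G-quadruplexes, short protein-binding motifs, nucleotide composition.

`lncortho` packages that strategy as a reusable, tested pipeline: gene
delineation from end-structure anchors, an identity-weighted
average-nucleotide-identity (ANI) statistic with archetype selection,
polyadenylation-signal (PAS) calling for the short isoform, TE annotation
under the 80-80-80 rule with presence/absence and excision calling,
self-complementarity detection, G-quadruplex/hexamer/composition profiling,
base-pair covariation, and promoter scanning with exact motif p-values.
Because real ortholog collections require external genome databases, the
package ships a synthetic-locus generator that plants all of these features
with recorded ground truth and evolves them along a user-supplied phylogeny,
so every stage can be validated end to end by parameter recovery.

# The core statistics and procedures

## Local homology search

All homology-based stages run on one in-repo seed-and-extend local aligner
(`local_align()`): exact word seeds (word size 11) extended in both
directions under affine gap scores (match +1, mismatch −2, gap open −5, gap
extend −2) with x-drop termination. Minus-strand hits are searched on the
reverse complement and reported in forward coordinates. `N` never matches
anything, which keeps identity estimates conservative on gapped assemblies.
Each high-scoring pair (HSP) carries coordinates, percent identity over
alignment columns, length, and score.

Two numerical choices matter:

* **x-drop = 50.** Crossing an indel of length $k$ costs $5 + 2(k+1)$
  before scores can recover, so an x-drop of 20 would terminate every
  extension at gaps longer than ~7 bp and split any repeat containing a
  moderate indel into fragments that fail coverage filters downstream. 50
  bridges indels up to ~21 bp while still cutting extensions through random
  sequence within a few dozen bases (expected score drift −1.25/bp).
* **Duplicate suppression is diagonal-aware.** A candidate HSP is dropped
  only when its query and subject spans are ≥90% contained in a better HSP
  *and* it lies in the same diagonal band. Without the diagonal condition,
  genuine repeat-induced off-diagonal self-matches (exactly what the ANI
  clamp and self-complementarity stages need) would be swallowed by the main
  diagonal.

On short inputs the aligner is verified against an independent
Smith-Waterman oracle; note that equally optimal local alignments are not
unique (end segments with net score zero can be included or not), so the
oracle comparison asserts exact score equality in general and identity
agreement on constructed unique-optimum cases.

## ANI and archetypes

For genes $G_1, G_2$ with lengths $L_1, L_2$, every local hit longer than
100 bp (strictly) contributes its identity-weighted length
$w = \mathrm{pident}/100 \times \mathrm{length}$, and

$$\mathrm{ANI} = \frac{1}{2}\left(\frac{\sum w}{L_1} + \frac{\sum w}{L_2}\right)\times 100.$$

All hits are summed, so repeat-rich genes can exceed 100%; the value is then
clamped to 100 and flagged, and an optional mode merges query-side
overlapping hits first (off by default — the literal sum is the primary
definition). Whether reciprocal/overlapping hits should be deduplicated
before summation is genuinely ambiguous; exposing both behaviors makes the
difference measurable instead of silent.

Archetypes — maximally mutually dissimilar representatives used for
shared-feature discovery — are selected by farthest-first greedy on
$d = 100 - \mathrm{ANI}$: start from the most distant pair, repeatedly add
the gene maximizing its minimum distance to the selected set, with
deterministic lexicographic tie-breaks. Max-min diversity selection is
NP-hard and the greedy is a 1/2-approximation, *not* an exact solver: on
random dissimilarity matrices it returns a non-optimal subset in roughly a
quarter of cases even when the optimum is unique. The package therefore also
exports `archetype_maxmin_exact()`, a brute-force optimum for small inputs,
used as the oracle in tests and available whenever $\binom{n}{k}$ is small.
On cluster-structured matrices (the realistic case: orders of similar
orthologs separated by deep divergence) greedy and exact coincide and pick
one member per cluster.

## PAS calling

The short isoform's 3' end is defined by the canonical hexamer `AATAAA`.
The position of a reference ortholog's PAS is projected into each gene
through the best covering local hit (offsets mapped exactly through a gapped
realignment, with a Smith-Waterman fallback), and a call is made only when
*exactly one* motif occurrence lies within ±110 bp of the projection; zero
occurrences give a no-call with reason `absent`, several give `ambiguous`.
The ±110 window is anchored on the motif start (the anchoring convention is
not standardized; motif-start is chosen and used consistently). Alternative
signals are enumerated within ±600 bp of the called main PAS; the marsupial
two-PAS mode is the same scan labelled `marsupial_pair`, expecting a second
signal ~500 bp away. Projection failure is deliberately distinct from "no
PAS": the former means no homology near the reference position, and
propagates as a no-call rather than an exception. An optional positional
rescue (a single motif in gene offsets 3,000–4,500, where short-isoform
lengths concentrate) is off by default.

## TE annotation, positional profiles, excision

Candidate TE hits (every library consensus against the gene, both strands)
must pass the classic 80-80-80 rule: alignment ≥80 bp, identity ≥80%, and
≥80% of the consensus covered (coverage is computed on the consensus span).
Overlaps are resolved greedily by descending
$\mathrm{pident}\times\mathrm{length}$ with deterministic tie-breaks
(higher identity, then leftmost start, then name) — simple, reproducible,
and checkable: the accepted set is an independent set in the overlap graph,
maximal, and priority-consistent. Positional profiles assign each accepted
TE to the 5%-of-gene-length bin containing its interval midpoint (midpoint
for extended features; point-like motif occurrences elsewhere bin by start —
the asymmetry is intentional and documented).

Presence/absence across orthologs anchors each TE locus by its ±200 bp
flanks. A leaf without the annotation is called `absent` only when both
flanks are found *and* they abut with at most 10 bp of residue (a clean
excision junction); a flank that fails to anchor leaves the locus
`unresolved`, never absent. An excision is flagged when exactly one leaf
inside the carriers' clade lacks the locus with a clean junction — this also
correctly refuses to flag subtree-specific insertions, whose non-carriers
lie outside the carrier clade. The 10 bp junction tolerance is a judgment
call: excisions are usually identified visually, but an automated pipeline
needs a numeric criterion.

## Self-complementarity

Reverse-complementary region pairs within a gene (IRAlu-like when close) are
the minus-strand hits of the gene aligned against itself; plus-strand
self-hits are never searched, so the trivial full-length identity is
excluded by construction. Every hit appears twice (once mirrored); mirror
duplicates are collapsed so each planted pair is counted once. Pairs
separated by ≤2,000 bp are classed `proximal` (the human IRAlu geometry,
arms ~130 bp apart, sits comfortably inside), the rest `distal`. The 100 bp
minimum arm length transfers the ANI hit threshold; it is a transferred
default, not an independently motivated constant.

## G-quadruplexes, hexamers, composition

The G4 detector is the canonical pattern — four maximal G-runs of ≥3
separated by loops of 1–7 nt — scanned left-to-right greedily per strand
with non-overlapping hits. A run of ≥3 G cannot sit inside a loop; shorter
G-runs can. This is deliberately the portable pattern definition rather than
a scoring-tool reimplementation: scored predictors' counts depend on tool
versions and internal thermodynamic heuristics, while the pattern is exactly
testable against a brute-force oracle.

Hexamer profiles count all 4,096 keys over sliding windows (windows touching
`N` are skipped and reported); queried motifs (RNA alphabet accepted, U→T)
are additionally binned into 10% positional bins. Shared-motif discovery is
intersection semantics: hexamers present at least `min_per_gene` times in
*every* profiled gene, ranked by the minimum count across genes. Nucleotide
usage reports overall and per-5%-bin base percentages with `N` excluded from
denominators.

## 3'-end structures and covariation

Sub-element boundaries (triple-helix motif, hairpin, linker, tRNA-like) are
measured by mapping a reference layout through gapped alignment; an element
that fails to map is reported absent without failing the others. Short
elements are aligned across orthologs with a reference-anchored multiple
alignment (every row globally aligned to the first sequence, insertions
padded) — adequate for well-conserved elements, and explicitly not a
general progressive aligner; externally produced alignments are accepted
as input.

Column conservation calls a column identical when one base has frequency 1
among non-gap rows and at least half the rows are non-gap. Covariation
classifies each row's base pair at structure-paired columns as canonical
(AU/UA/GC/CG/GU/UG) or inconsistent; compensatory pairs are canonical pairs
differing from the majority canonical pair. The score,

$$s = \frac{n_\text{canonical} - n_\text{inconsistent}}{n_\text{rows}} \in [-1, 1],$$

credits compensatory double substitutions (they stay canonical) and
penalizes pairing-breaking changes; gapped rows dilute toward zero. The
statistic is defined here precisely so it is exactly computable and
hand-checkable, in place of external covariation-coloring tools.

## Promoter scanning

PWMs are read from JASPAR count or MEME probability records (probabilities
are converted back to counts via `nsites` so both routes yield identical
matrices) with a 0.1 pseudocount per cell. Window log-odds scores are
discretized on a 1/1000-bit lattice and the *exact* null distribution under
the background model is computed by dynamic programming, giving p-values
with no sampling error; at that granularity, width-20 matrices stay exact to
~1e−6 in p, and for widths ≤8 the DP is verified against full enumeration
of all $4^w$ words. Hits require $p < 10^{-4}$ on either strand of the 1 kb
promoter window upstream of the TATA-box, deduplicated to the better strand
per position. The background defaults to uniform 0.25 (a per-sequence
background is optional). Shared TFs are those with at least one hit in ≥65%
of ortholog promoters (inclusive threshold: 7 of 10 qualifies). The GO join
is plain term counting over a user-supplied TF→term table; no enrichment
statistics are computed or implied.

# The synthetic-locus generator

`build_root_locus()` plants, on one strand of one contig:

| feature | default | notes |
|---|---|---|
| divergent gene A | 21,000 bp | NEAT1-like |
| conserved gene B | 7,000 bp | MALAT1-like, evolves at 0.3× |
| intergenic distance | 36,755 bp | gene A end → gene B start |
| TATA-box | `TATAAA` at each 5' end | substitution- and indel-protected |
| PAS | `AATAAA` at gene A offset 3,500 | sole motif in a ±600 bp guard zone |
| 3' block | helix motif 20 + hairpin 29 + linker 30 bp (gene A); 20+31+24 (gene B) | motif protected; hairpin/linker lengths fixed (no indels), sequences free |
| tRNA-like | 54 bp synthetic cloverleaf with known dot-bracket | planted stems give covariation signal |
| TEs | 6, wholly inside the 30–40% and 70–80% length bins | from a synthetic 6-family library (`*_syn` names) |
| inverted repeats | 2 pairs, 300 bp arms, spacers 1,000 and 5,000 bp | one proximal, one distal |
| G-quadruplexes | 4, near the two gene ends | canonical 21 bp pattern |
| GU tracts | 8 × (GT)₁₂ in the 3' 82–96% window | TDP-43-style binding motifs |
| core motifs | 30 isolated `TCTGTG` + 30 `CTGTGT`, central window | *isolated*, not tandem |
| background | A 0.28, C 0.19, G 0.22, T 0.31 | T-enriched, C-depleted |

Placement uses a collision registry; an infeasible packing raises an error
naming the colliding features. Two generator choices deserve explanation:

* **Core motifs are planted as isolated occurrences, not tandem repeats.** A
  tandem `(TCTGTG)ₙ` tract contains all six cyclic rotations of the repeat
  unit at nearly equal counts, so shared-motif discovery would face a
  six-way tie decided by noise. Isolated plants make the two intended
  motifs, and only them, enriched. GU tracts stay tandem (that is what a GU
  repeat is); their two rotations are both intended motifs.
* **The background is only mildly T-enriched.** With a strongly T-rich
  background, `TTTTTT` and friends reach expected counts competitive with
  planted motifs in a 21 kb gene; A 0.28/C 0.19/G 0.22/T 0.31 keeps the
  composition signature (T% > 25 > C%) testable while leaving planted
  motifs clearly separated from the background tail.

`evolve_along_tree()` applies Jukes-Cantor substitutions per site with
probability $\tfrac34\!\left(1-e^{-4ds/3}\right)$ on each branch of length
$d$, geometric-length indels (mean 3, capped at 50, rate 0.005 per site per
unit distance), and optional TE insertion/excision; excisions can also be
planted deterministically on named leaves. Truth coordinates are lifted
exactly through every edit. Per-branch RNG streams are derived by hashing
the child node name with the seed, so adding a leaf does not reshuffle the
others. JC69 is sufficient because only relative divergence matters for
validation; no selection, no context-dependence, no rate heterogeneity
beyond the conserved-gene factor — leaf truths are still exact, which is
the property the tests consume.

Protected zones go beyond the two motifs whose real counterparts show
perfect conservation (TATA-box, triple-helix motif): the planted PAS
hexamer is also held fixed, the guard zone is kept indel-free, and any
mutation that creates a stray `AATAAA` inside a guard zone is reverted.
This keeps the planted single-PAS condition — a stated property of the
generated data — true at every leaf, so PAS recovery tests measure the
caller, not motif birth/death along the tree.

**Default tree depths are a power calculation.** The two arms of an
inverted repeat diverge from *each other* at twice the root-to-leaf depth.
At depth 0.10 the expected arm-pair identity is ~82%, statistically
indistinguishable from the 80% detection threshold over 300 bp arms; the
default six-leaf tree therefore uses depths 0.055–0.07 (arm identity ~87%,
more than 3 binomial s.d. above threshold), keeping every planted feature
detectable in expectation so that recovery failures indicate detector bugs
rather than generator-induced decay.

What the generator does *not* emulate: assembly gaps and
sequencing error, rate heterogeneity among sites, selection on secondary
structure (covariation constraint is simulated only in dedicated test
fixtures), nested/fragmented TEs, segmental duplications, and real TE
consensus sequences (the library is synthetic and labelled as such).
Passing recovery tests therefore demonstrates correctness of the detectors
under the stated generative model, not performance on real genomes.

# Validation layout and problem sizes

The test suite validates each module against hand-computable cases and
independent oracles (Smith-Waterman for the aligner, brute-force pattern
enumeration for G4s, exhaustive $4^w$ enumeration for PWM p-values,
brute-force max-min subsets for archetypes), plus property-style invariants
(reverse-complement symmetry, threshold monotonicity, permutation
invariance) under fixed seeds. End-to-end parameter recovery runs 20
cohorts of the default six-leaf tree (120 leaves): gene boundaries within
±20 bp, all planted TEs/inverted repeats/PAS recovered, zero false
positives on feature-free control loci, summed TE profiles peaking in the
planted bins, and the four planted hexamers as the top shared motifs. The
closed-form check compares JC69 leaf identity and mean ANI against
$\tfrac14 + \tfrac34 e^{-4d/3}$ up to $d = 0.3$. `scripts/acceptance.R`
re-runs a five-cohort subset of the same recovery battery plus the analytic
worked cases and writes the results as JSON.

# Known limitations

* The aligner is a heuristic: ungapped word seeds mean homology below ~65%
  identity (no 11-mer exact matches) is invisible, and x-drop extension can
  trim low-identity HSP tails; ANI at high divergence is accordingly an
  alignable-fraction statistic, slightly above raw per-site identity.
* Greedy archetype selection is a 1/2-approximation; use
  `archetype_maxmin_exact()` when exactness matters and the input is small.
* The reference-anchored MSA degrades when rows are highly diverged from
  the reference; supply an external alignment in that regime.
* Percent-identity comparisons between equally optimal alignments are
  inherently ambiguous at the ±1–2 point level.
* The pipeline's per-contig anchor liftover does not implement the
  taxon-grouped MSA refinement a manual curation pass would add; an
  optional modal-boundary refinement over candidate ends is the closest
  in-package analogue.
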