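---
title: "Methods: discovering and dating genome-specific composite repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and dating genome-specific composite repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repscout)
```

# The problem

Allopolyploid cotton combines two parental chromosome sets (the A and D
subgenomes). The diploid D genome carries a composite repetitive element
that the A genome lacks entirely: a tandem-repeat (TR) array of ~133 bp
units, repeated a variable number of times, sitting next to a stable
conserved sequence (CS) of ~860 bp, the whole assembly harboured inside
degraded LTR retrotransposons. Because the element is present on every
D-subgenome chromosome and absent from every A-subgenome chromosome, it
doubles as a subgenome diagnostic: an assembly that places the motif on an
"A" chromosome has probably misassigned that segment.

repscout re-implements the discovery-and-characterization workflow as a
reusable pipeline: homology screening under the 80–80 rule, tandem-array
detection with unit-consensus training, constituent pairing into composite
motifs, consensus-accumulation profiling of host elements, paired-LTR
detection with Kimura two-parameter (K2P) insertion dating, chromosomal
distribution statistics, and synteny-block chaining. A fully ground-truthed
simulator generates a D-like/A-like genome pair so every stage can be
validated end to end without downloading any assembly.

# The models

## Substitution model and insertion dating

LTR retrotransposons insert with two identical long terminal repeats; each
copy then accumulates substitutions independently at rate $r$ per site per
year. The K2P distance between the paired LTRs,

$$d = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big],$$

with $P$ and $Q$ the transition and transversion proportions over ungapped
aligned columns, estimates the total divergence, and the insertion age is

$$T = \frac{d}{2r}, \qquad r = 1.3\times10^{-8}\ \text{subs/site/year}.$$

Outside the model's domain ($1-2P-Q \le 0$ or $1-2Q \le 0$) the divergence
is saturated and `k2p_distance()` raises an error rather than returning a
number; such elements are counted as undated.

The simulator is the generative counterpart of the same model:
`mutate_k2p(seq, d, kappa)` draws per-site substitutions with transition
and transversion probabilities chosen so that the *expected estimated* K2P
distance equals `d` at transition/transversion rate ratio `kappa` (default
2). This identity — generator and estimator are exact inverses in
expectation — is what the age-recovery tests exercise.

## The 80–80 rule

Two sequences are treated as copies of the same repeat family when a local
alignment covers at least 80% of the query length at at least 80% identity,
both thresholds inclusive. "Matching ratio" is mapped to query coverage and
"similarity" to alignment identity; this follows the classical 80–80
reading (80% of the length, 80% identity). The thresholds are parameters
everywhere (`passes_80_80()`, `motif_definition()`, `cluster_families()`),
never constants.

# Algorithms and numerical choices

## Seed-and-extend search

`search_genome()` indexes query k-mers (default $k = 12$), streams each
chromosome on both strands, and extends every seed on a not-yet-covered
diagonal. Extension is two-phase, as in BLAST: a cheap ungapped x-drop
extension first, and a banded affine-gap Smith–Waterman around the seed
diagonal (band half-width 32, x-drop 20) only when the ungapped score
reaches a trigger. Scoring is match $+1$, mismatch $-1$, and a gap of
length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$ with open 2, ext 1.
`N` never matches anything, including itself — a conservative choice that
keeps assembly gaps from inflating identity. With a generous band and
x-drop the banded extension is exhaustive, which is how the test suite can
demand exact score agreement with an independent Smith–Waterman
implementation on homologous pairs.

## Tandem arrays

`detect_arrays()` finds candidate periods by lag-match autocorrelation:
for each candidate period $p$ it computes the 0/1 profile of positions
agreeing with themselves shifted by $p$ and calls runs whose rolling mean
over one period stays at or above the identity floor (default 0.75).
Overlapping candidates are clustered; when $p$ and a multiple of $p$ both
explain a locus the smaller period wins if its signal is within 2 points —
the canonical minimal period. Two guards matter in practice:

* a TRF-style array score (lag matches $+2$, mismatches $-7$, minimum 50)
  suppresses the short chance self-matches any random sequence contains
  once units as short as 10 bp are allowed;
* boundaries are trimmed to the outermost run of at least five consecutive
  lag matches, because the window-run detection overshoots by a few bases
  into flanking sequence.

Copy number is reported real-valued (span / unit length) — arrays end
mid-unit — alongside an integer unit content (its floor).
`train_unit_consensus()` partitions the array into unit frames, takes a
positional column-majority consensus, re-aligns every frame to it and
votes once more; the consensus always has exactly the unit length.

## Composite motif calling

`scan_constituents()` deliberately does *not* use de novo array detection
genome-wide: TR hits are unit-consensus matches passing the 80–80
thresholds, merged into arrays (same chromosome and strand, gap at most
half a unit), which is both faster and anchored to the family definition.
CS hits are 80–80-passing hits of the CS consensus merged per locus.
`pair_constituents()` pairs same-chromosome, same-strand TR and CS hits
greedily by smallest gap (leftmost wins ties; each hit used once) with a
default `max_gap` of 200 bases. The published structure shows the
constituents abutting but never quantifies a gap; 200 bases is our
documented default, exposed in `motif_definition()`. The constituent order
is not assumed — the simulator flips element orientation with probability
0.5 precisely so that callers must handle both.

## Consensus accumulation and plateau calling

`consensus_accumulation()` star-aligns every instance to a reference
(pairwise banded global alignments; $O(n)$ alignments replace a full
multiple alignment, which reproduces the conserved-core plateau without an
MSA engine) and counts, per reference column, the instances agreeing with
the column majority. `plateau_region()` first smooths the per-column
agreement with a 50-column rolling mean: single-column agreement is
binomially noisy (with 20 instances and a flank whose per-copy divergence
is 0.4, roughly 3% of flank columns reach 90% agreement by chance, and a
few core columns dip below it), whereas after averaging the core and
flank separate by many standard errors. Smoothed columns at $\ge$ 90% of
the instance count are merged across dips of up to 30 columns, and blocks
narrower than 100 columns are dropped — conserved constituents are
hundreds of bases, chance clusters tens.

## LTR pair detection and unbiased dating

`detect_ltr_pairs()` searches the two ends of each candidate interval for
the highest-scoring pair of similar direct repeats (seed size 6 — the
repeats may be heavily diverged — band 50, x-drop 100) subject to length
bounds (100–3000 bp per LTR, element span 1–15 kb) and a similarity floor.

A subtlety we found during validation: the maximal-scoring local alignment
of two diverged copies is *not* an unbiased sample of their divergence. It
selects the match-richest segment, underestimating $d$ by ~15% for pairs
30 million years old. The dating path therefore only uses the local hit to
locate the pair, then:

1. extends both intervals along the hit diagonal (up to 400 bp past each
   hit end),
2. re-aligns with stiff gap costs (open 8, ext 4) so the measurement
   alignment cannot wander between diagonals chasing chance matches,
3. re-estimates the LTR boundaries as the contiguous region where an
   80-column rolling identity stays above the midpoint between the core
   identity and the 25% random baseline, and
4. counts $P$ and $Q$ over that region's interior, discarding 50 columns
   at each end so the distance is decoupled from the boundary-detection
   columns. Gap and `N` columns are excluded, standard K2P practice.

With this estimator, simulated elements with 1 kb LTRs and ages uniform on
1–30 million years are dated with a mean absolute relative error of
6–8% and no detectable systematic bias.

The default similarity floor (0.70) targets confident pair calling in
noisy genomes. It is worth being explicit that a 30-million-year-old pair
is only ~55% identical at $r = 1.3\times10^{-8}$, so a dating survey that
must include such old elements needs a lower floor; the age-recovery
analyses in this package run at 0.45. Elements without a qualifying pair
are retained in motif-level outputs but excluded from dating, mirroring
the empirical pattern that most degraded elements cannot be dated.

`cluster_families()` is single-linkage under the 80–80 rule evaluated on
both sequences of each pair (coverage of *each* sequence at least 80%);
the partition is invariant to input order.

## Distribution statistics

`chi_square_uniformity()` tests proportionality of insertion counts to
chromosome length: $E_i = N L_i / \sum L$, $\chi^2 = \sum (O_i-E_i)^2/E_i$
with $k-1$ degrees of freedom and an upper-tail p-value
(`stats::pchisq`), flagging expected counts below 5. Assembly lengths are
used for $L_i$ (cytological sizes are not available to a sequence-only
pipeline). `window_density()` tiles chromosomes with non-overlapping
500 kb windows — counts in tiling windows are identical to a stride-equal
"sliding" window — and assigns features by start coordinate, which is
unambiguous for boundary-spanning features. `find_synteny_blocks()` seeds
anchors from 500 bp tiles of one segment, keeps 80–80-passing best hits,
chains the heaviest collinear subset by weighted
longest-increasing-subsequence, and splits blocks where the diagonal
offset jumps by more than 1 kb or anchors are more than 5 kb apart — the
breaks are exactly where insertions or deletions (such as the loss of an
element on one homolog) sit.

# The simulator: what it emulates and what it does not

`simulate_genome_pair()` plants, on an i.i.d. background of configurable
GC (default 0.35, a plant-genome-like value), three feature classes drawn
from shared family templates: full motifs inside host LTR elements,
solitary TR arrays, and solitary CS copies, assigned to chromosomes
proportionally to length. Defaults are the study conditions: 13
chromosomes of 1 Mb, 20 full motifs, 5 + 5 solitary constituents, 133 bp
units repeated 2–21 times, an 860 bp CS, 1 kb LTRs, ages uniform on 1–30
million years, $r = 1.3\times10^{-8}$, transition/transversion ratio 2.
Each tandem unit receives an independent 2% divergence (arrays are
imperfect, so consensus training is non-trivial) and the CS 2% per
instance; LTRs and the internal backbone degrade with age at $r\,T$ per
copy while the motif core stays conserved — the conserved-core-in-
degraded-host structure the consensus-accumulation profile detects. 65%
of host elements (47/72 in the motivating system) lose one LTR and cannot
be dated. The A-like genome is the identical background with every
planted footprint deleted exactly, giving the clean flank collinearity of
a presence/absence contrast; optional unrelated A-side insertions and
decoy microsatellites are available as stress tests.

What the simulator does *not* model, and hence what passing tests cannot
show about real data: indel evolution inside LTRs (substitutions only),
background repeats and segmental duplications, insertion-site preference,
recombination between elements, and background divergence between the two
genomes (real A/D backgrounds have diverged substantially; the clean
contrast isolates the presence/absence signal). Boundary-accuracy results
(±20 bp) in particular lean on the indel-free backbone.

# Problem sizes

The validation suite runs five full-scale simulated pairs (13 × 1 Mb
chromosomes, 30 planted features each) for motif recovery, 100 elements
for age recovery, 1000 analytic replicates for type-I calibration, 20
instances for the consensus plateau, and a 26-chromosome synthetic
tetraploid for misassembly detection; the whole suite completes in a few
minutes on one core.

# Known limitations

* The seed-and-extend search is exact only when the band covers the
  optimal alignment's diagonal drift; genome-scale defaults trade a
  narrow band for speed, as BLAST does.
* Dating assumes the K2P model and independent sites; saturated pairs
  (identity near the random baseline) are reported undated rather than
  extrapolated.
* `detect_arrays()` is deliberately not a full stochastic-model tandem
  finder; units shorter than 10 bp (microsatellites) are out of scope.
* The misassembly diagnostic flags chromosomes, not breakpoints; synteny
  blocks localize the lost locus only at anchor resolution.
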