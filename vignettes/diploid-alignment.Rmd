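---
title: "Recombination-aware distances between diploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination-aware distances between diploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipalign)
```

## The model

A diploid genome consists of two homologous haplotype sequences. `dipalign`
represents a diploid as a *pair-wise alignment* `(S^A, S^B)`: two equal-length
rows over the alphabet plus the gap `'-'`, such that removing gaps from either
row recovers a haplotype, and no column carries a gap in both rows. The cost
of an alignment is the sum of its column costs `C(a, b)` under a cost model
with `C(a, a) = 0`, symmetric positive substitution costs, and a positive
indel cost; the edit distance `D(A, B)` is the minimum cost over all
alignments (`edit_distance()`).

Diploids evolve through mutation *and* recombination, and phased predictions
additionally contain *switch errors* — positions where the assignment of
variants to the two haplotypes flips relative to the truth. A distance that
charges every switch as if it were a run of sequence differences wildly
overstates dissimilarity. The remedy is the *recombination* operator: given a
bitvector `I` over alignment columns, column `i` keeps its orientation where
`I[i] = 1` and exchanges its two symbols where `I[i] = 0`
(`apply_recombination()`). Positions where `I` changes value are the *switch
positions* — the phasing-relevant summary, and the one we report, because it
is invariant under complementing the mask (which merely renames the two
output haplotypes). We use the "1 = keep" convention internally; reporting
switch positions sidesteps any ambiguity about what the raw bits mean.

Three distances arise:

* **Pair of haploids to diploid** (`hap2dip_distance()`): the minimum of
  `D(A', X) + D(B', Y)` over all recombinations `(A', B')` of the diploid,
  against two fixed haploid sequences `X`, `Y`. Solvable exactly by dynamic
  programming over cells `(i, j, k)` — prefixes of `X`, `Y` and of the
  alignment columns — in `O(NML)` time. When the two symbols of a consumed
  column differ, every insertion/substitution case appears in both
  orientations; when they agree the duplicated cases collapse. Because
  `C('-','-') = 0`, gap-bearing columns need no special cases.
* **Synchronized diploid to diploid** (`sync_distance()`): both diploids are
  alignments; the first may recombine freely, while the second acts as a
  *guide* whose own alignment is kept fixed and whose consumption drives the
  two output alignments in lockstep. The guide is encoded by its *guiding
  function* `h(z) = (h_i(z), h_j(z))`, the numbers of non-gap symbols
  consumed in each row after `z` columns (`guiding_function()`); `h` is an
  equivalent encoding of the alignment (`guiding_to_alignment()`). The DP
  runs over `(z, k)` in `O(L¹L²)` time with a step-cost function (`zeta()`)
  dispatched on the per-column increment `Δh ∈ {(1,1),(0,1),(1,0)}`, each
  diploid-consuming step minimized over the two orientations.
* **General diploid to diploid** (`brute_force_two_sided()`): both sides
  recombine. No efficient algorithm is known; the package provides exhaustive
  mask enumeration for small instances only (capped, overridable), as a
  reference point and test oracle. `brute_force_one_sided()` plays the same
  role for the cubic DP.

Synchronization *restricts* the one-sided search space, so on any instance

```
two_sided  <=  one_sided  <=  min fixed pairing,      one_sided  <=  sync.
```

The synchronized measure is directional — `sync_distance(a, b)` recombines
`a` against guide `b` — and need not equal the reverse call; the CLI offers
`--symmetric` to take the minimum of both directions.

```{r example}
wc <- cost_model(mismatch = 10, indel = 1)
d1 <- pairwise_alignment("tc", "ag")
d2 <- pairwise_alignment("ngc", "atv")
hap2dip_distance(d1, "ngc", "atv", wc)$distance   # one-sided: 6
brute_force_two_sided(d1, d2, wc)$distance        # both sides recombine: 2
sync_distance(d1, d2, wc)$distance                # synchronized: >= one-sided
```

This weighted instance (substitutions ten times an indel) is the worked
counterexample showing that one-sided recombination cannot always reach the
general optimum: recombining the *second* alignment at its middle position
yields haplotypes `ntc`/`agv` at total cost 2, while recombinations of the
first alignment alone can do no better than 6.

## The banded variant and what "monotonicity" really is

`banded_edit_distance()` and `sync_distance_banded()` restrict the DP to
diagonals near the hull of the start and end diagonals, with band radius
`ceiling(t / (2 * cmin))` for a threshold `t`, where `cmin` is the smallest
strictly positive single-column cost (for unit costs this reduces to the
classic `{-t/2, ..., t/2}` zone). Any path that leaves the band must perform
more than `t` worth of strictly positive off-diagonal steps, so once the
computed value is at most `t` it is provably exact; `t` starts at the
length-difference lower bound and doubles until that test succeeds, and the
geometric series of zone sizes keeps total work at `O(ND)`.

The correctness of the pruning rests on one fact: every step of the
synchronized DP that advances only the guide (`z`) or only the diploid (`k`)
has strictly positive cost, because the guide haplotypes contain no gaps and
no diploid column holds two gaps. The boundary row and column of the table
are therefore strictly increasing, and `D[z,k] >= cmin * |z - k|`. Note that
*full* strict row/column monotonicity of the table (`D[z,k] > D[z-1,k]`
everywhere) cannot hold for any global-alignment table: identical diploids
have `D[L¹,L²] = 0` while the boundary cells are positive, and rows
generally decrease toward the main diagonal before rising again — exactly as
in the classic edit-distance matrix. `check_monotonicity()` implements the
strict row/column check so that this boundary between the true and the
too-strong property is itself testable; the test suite exhibits the
counterexample and verifies the properties the banded variant actually
needs, including banded/full equality on hundreds of randomized instances.

## Numerical and design choices

* **Boundary layers.** The recurrences are stated for interior cells; empty
  prefixes force `V[i,j,0] = (i+j) * indel`, `V[0,0,k]` accumulating the
  gap-against-column costs, and analogously `D[z,0]`/`D[0,k]` for the
  synchronized DP. The implementation simply guards each case by predecessor
  validity, which reproduces these layers.
* **Tie-breaking.** Deterministic everywhere: edit-distance traceback
  prefers diagonal, then deletion, then insertion; the cubic DP prefers the
  lowest-numbered case, which keeps the original orientation on ties;
  orientation-free columns (both symbols equal) inherit the nearest decided
  orientation so masks carry no spurious switches. Brute-force enumeration
  is in canonical numeric mask order, ties to the lowest value.
* **Recombination penalty.** The Conclusions-level extension of charging
  each switch is implemented in the synchronized DP: orientation becomes a
  second DP state bit (two layers), each diploid-consuming transition pays
  `costs$penalty` when its orientation differs from the previous consumed
  column's, and the first consumed column is free. With penalty 0 the layers
  coincide and orientation is a free per-column choice, matching the free
  recombination model exactly; as the penalty grows the distance increases
  monotonically to the best single-orientation (no-switch) cost. The cubic
  DP is kept penalty-free; the penalty is scoped to the synchronized
  measure.
* **Degenerate inputs.** Empty sequences and zero-length prefixes are
  handled by the boundary layers; double-gap columns are rejected up front
  with the offending column named (they would break the positivity argument
  above); `'.'` as a gap dialect is rejected rather than guessed; input is
  case-folded to lower case by default (disable with `case_fold = FALSE`);
  any single-character alphabet is accepted, with symbols outside an
  explicit cost matrix falling back to the default mismatch cost.
* **Memory.** Distance-only mode of the cubic DP keeps two `k`-planes and
  handles thousands of positions; traceback stores the full backpointer
  cube and is intended for moderate sizes (it refuses absurd allocations).

## What the simulator emulates

`simulate_table2_pair()` reproduces the evaluation design in which the
synchronized distance should recover planted mutations exactly: a uniform
random reference (default length 10^4), heterozygous variants at rate
0.01/base assigned to one of two founder haplotypes, each diploid copying
the founders block-wise (blocks of 200 bases, orientation switching with
probability 0.5 at each boundary — free recombination), and a fixed number
of extra substitutions, each on one uniformly chosen strand. Mutations are
kept non-overlapping and at least 5 bases from every variant by rejection
sampling, which is what makes `sync distance == mutation count` provable
for substitutions; `allow_collisions = TRUE` reproduces the unconstrained
setting, where planted and recovered counts can drift apart slightly.
`simulate_table1_pair()` instead mutates four reference copies
independently (rate 0.005/base per copy, 90% SNPs / 10% single-base
deletions) and pairs them into two diploids. The haplotype pair of each
diploid is aligned by optimal unit-cost traceback with deterministic
tie-breaking; a fixed seed yields a byte-identical record.

Defaults were chosen once to give realistic evaluation ratios (about one
heterozygous variant per 100 bases, a few mutations per 10^3 bases) on a
synthetic reference. The simulator does **not** emulate realistic mutation
spectra, indel length distributions, repeat structure of real chromosomes,
or sequencing error, so passing tests demonstrate algorithmic correctness
of the distances on the generative model — not calling accuracy on real
data. The variant-rate / SNP-fraction mix is configurable and not claimed
to match any particular genome.

The test suite exercises the distances at the following scales, chosen so
the whole suite runs in well under a minute of DP time: oracle equivalence
on hundreds of instances with up to 8 alignment columns (where `2^L` mask
enumeration is exact), banded-versus-full equality up to length 200, and
twenty seeded replicates of the length-10^4 simulation with 20 planted
substitutions, every one of which is recovered exactly while the naive
fixed-pairing Levenshtein distance is several-fold larger.

## Limitations

* The general two-sided distance is only available by exponential
  enumeration; solving it efficiently is an open problem.
* The synchronized measure recombines only its first argument and keeps the
  guide's own alignment fixed; where that alignment places gaps
  ambiguously, the synchronized distance can exceed the unconstrained
  optimum (this is inherent to the definition, and the reason the ordering
  chain above is one-directional).
* Affine gap penalties, local alignment and similarity (maximization)
  scoring are out of scope; only the distance formulation is implemented.
* The trio-phasing generalization (aligning a child's diploid against two
  parental alignment DAGs) is not implemented.
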