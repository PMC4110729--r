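---
title: "Methods: noisy Boolean network landscapes and multistable switches"
author: "switchscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noisy Boolean network landscapes and multistable switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscape)
```

## The model

A gene regulatory network is represented as a synchronous Boolean network:
`n` genes, each either expressed (1) or silent (0), each regulated by an
ordered list of input genes through a truth table. All genes update
simultaneously, so the network is a deterministic map `D` on the `2^n`
states. Trajectories of `D` must revisit a state within `2^n` steps and
therefore end in an attractor — a fixed point ("point attractor") or a
cycle ("cyclic attractor"). In the differentiation picture, each attractor
stands for a cell type and its basin for the set of expression states that
relax to that type; differentiation is noise-driven movement between
basins across an epigenetic landscape.

States are encoded as integers with gene 1 on the least-significant bit.
Input lists are stored most-significant bit first, so the *last* listed
input is the low-order ("2^0") slot; this is the slot switch motifs use
for their partner gene. Both conventions are arbitrary; they are fixed
here once and used by every reader, writer and operation.

`find_attractors()` enumerates all `2^n` states with memoization, which is
exact and cheap up to the default cap of `n = 20`. Attractors are ordered
by their smallest member state, making every downstream table reproducible.

## Gene-expression noise and the transition matrix

Noise is modelled as independent per-gene flips: in one time step each
gene flips with probability `p_e`. If no gene flips (probability
`(1 - p_e)^n`) the network takes its deterministic step `D`; if any gene
flips, the state jumps to the flipped state. For states `x != y` with
Hamming distance `h`:

```
p(x -> y) = p_e^h (1 - p_e)^(n - h)  +  (1 - p_e)^n [y = D(x)]
```

and the only self-mass is `(1 - p_e)^n` when `x` is a fixed point of `D`.
Rows then sum to 1 exactly (checked to 1e-12 in the tests). Two noise
conventions circulate in the Boolean-network literature — "the flip
replaces the update" versus "flip, then update". We implement the first,
the convention of Shmulevich-style gene-perturbation models, throughout,
including in the Monte-Carlo simulator, so all three computational routes
share one process. Because the flip kernel has full support, the chain is
irreducible for any `0 < p_e < 1` and every passage time below is finite.

`p_e` defaults to 0.01 — small enough that deterministic relaxation
dominates (for `n = 10`, a step is flip-free with probability ~0.90),
large enough that attractor transitions happen on scales of `10^2`–`10^6`
steps where the landscape structure is resolved. All outputs echo the
value used, and the region statistics below are conditional on it.

## Mean first passage times

The first-passage probability `F_k(x, y)` — first visit to `y` at step
`k` — obeys `F_1 = p_xy` and
`F_k(x, y) = sum_{z != y} p_xz F_{k-1}(z, y)`. The mean first passage
time is `sum_k k F_k`. Summing that series is the *definition*, but not
the computation: `mfpt_states()` solves the absorbing-chain linear system

```
m_x = 1 + sum_{z not in T} p_xz m_z
```

for a target set `T`, which equals the series exactly and costs one dense
LU solve. Attractor-to-attractor MFPTs average `m` uniformly over the
source attractor's cycle states (the uniform weighting is a convention;
cyclic attractors visit their states equally often under `D`). The
diagonal is 0 by convention.

Three independent routes to the same number form the module's correctness
triangle, exercised in the test suite: the linear solve, the truncated
series (`mfpt_series_oracle()`, tail mass below 1e-9 or `10^5` terms),
and direct stochastic simulation (`mfpt_monte_carlo()`), with agreement
required to 1e-6 and 3 standard errors respectively. On the one-gene
identity network the closed form `MFPT(0 -> 1) = 1/p_e` pins all three.

Dense linear algebra is used throughout with a default cap of `n = 12`
(the flip kernel is structurally dense — every state reaches every other
in one step — so sparse solvers buy nothing; the cap can be raised
explicitly to 14 at `4^n` memory cost).

## Critical random networks

Random networks are drawn with fixed in-degree `q` (default 2), inputs
sampled without replacement (self-inputs allowed — the switch motifs
themselves rely on feedback), and truth-table entries i.i.d.
Bernoulli(`p_N`). The expected one-step spread of a single-bit
perturbation is the sensitivity `s = 2 q p_N (1 - p_N)`; `s = 1` is the
critical line between order and chaos, where real regulatory networks
appear to sit. `critical_bias(q)` returns the lower root of
`2 q p (1 - p) = 1` (sparse expression; the upper root is available), and
`empirical_derrida_sensitivity()` validates generated ensembles by Monte
Carlo — critical ensembles average spread 1.0 within sampling error. At
`q = 1` the sensitivity cannot exceed 1/2; the bias maximizing it (0.5)
is returned with a warning rather than pretending criticality.

## The four switches

The switch motifs are pairs of genes that mutually inhibit, in four
flavours: the toggle/bistable switch `BS` (`f = other | !partner`), plain
mutual inhibition `MI00` (`f = other & !partner`, the "other" input being
an external activator), and mutual inhibition with one (`MI0+`) or two
(`MI++`) positive self-feedback loops, where the activating input is the
gene's own output. In `MI++` the pair forms a closed two-gene island with
`u' = u & !v`, `v' = v & !u`: three fixed points (both off, exactly one
on), the tristable switch.

The switches' conventional truth tables `[1,1,0,1]` and `[0,1,0,0]`
index the input patterns with the partner bit written first — the
circuit diagrams' reading order; in this package's
high-bit-first storage the identical functions read `[1,0,1,1]` and
`[0,0,1,0]` (`motif_definition()` returns both spellings). The choice of
bit order is not cosmetic: read the other way, the tables would describe
partner-*activation*, the embedded pairs would not be multistable, and
(we verified on pilot ensembles) the landscape effects of embedding
vanish or invert. The inhibition reading is the one consistent with the
motifs' biology and with their described attractor counts, and it is the
one implemented.

Embedding replaces the truth tables of two randomly chosen nodes and
cross-wires each node's `2^0` slot to its partner; the high slot becomes a
self-loop where the motif has positive feedback (first node for `MI0+`,
both for `MI++`) and otherwise keeps its original source, which plays the
role of the external signal. Nothing else in the network changes. Chosen
nodes with in-degree other than 2 are truncated or extended to degree 2
first (recorded in the embedding record); with the default `q = 2`
generator this never triggers. Standalone motif networks use the same
wiring with external slots clamped to a constant (default 0; `MI00` needs
an active signal, `clamp = 1`, to show bistability — in isolation with no
signal both genes simply switch off).

## Landscape regions

For each unordered attractor pair the direction with the smaller MFPT is
*forward* (ties keep the lower-index orientation and are flagged). A pair
is **separate** when `forward >= 10^3` — even the easy direction is slow,
a high barrier in both directions, the signature of stabilized, mutually
inaccessible cell types. It is **directional** when `reverse/forward >=
10` while the forward move is fast — one-way traffic, the signature of a
differentiation step. The `10^3` cut-off matches the default pruning
threshold for MFPT graphs (`prune_mfpt_graph()`); it and the ratio 10
are conventions rather than estimates, so both are explicit parameters
echoed into every output. Raising the separation threshold shrinks the
separate set monotonically.

Ensembles are summarized on two scales: the fraction of pairs with a
label, and the mean count of labelled pairs per network. The distinction
matters because embedded switches multiply attractors — two-switch
networks yield several times more attractor pairs than bare networks — so
a real enrichment visible on the density-plot (count) scale can be
diluted away on the fraction scale. Density grids (`density_grid()`)
histogram pairs over `(log10 forward, log10 reverse)` with 40x40 bins by
default, and normalized grids can be differenced to show where one
network type places more mass than another.

## Alternative barrier measures

`transitory_flip_matrix()` implements the cheap perturbative measure:
every single-bit flip of every attractor state is relaxed noise-free and
the destination attractor tallied; `P[i, j]` is the fraction of flips
from attractor `i` landing in `j`. Flips that relax home are kept in
`P[i, i]`, so rows sum to 1 exactly (the alternative — dropping them from
the denominator — would leave rows summing below 1 and is not used).
`attractor_hamming()` lifts Hamming distance to attractors as the mean
over cross pairs of cycle states (a minimum variant is available);
unlike MFPT it is symmetric by construction, which is exactly why it
cannot capture directionality. `barrier_measure_study()` tabulates all
three measures over generated ensembles, and `barrier_correlation()`
reports Pearson r with a least-squares line. Across critical ensembles
the flip measure falls as MFPT rises (negative regression slope), and
Hamming distance correlates only weakly positively with the mean of
forward and reverse MFPT — network dynamics, not state-space geometry,
dominates the barriers.

## The ensemble protocol

`run_ensemble()` runs nine network types: bare critical networks, and one
or two embedded copies of each switch. Per accepted network: generate,
embed, enumerate attractors, reject if fewer than 5 attractors (networks
this small are usually rejected; acceptance runs ~10-30% depending on
type — embedded switches, by multiplying attractors, are accepted much
more often), then compute the full MFPT matrix and classify all pairs.
Each type draws its RNG stream from the master seed and the type's
canonical index, so any type reproduces bit-identically in isolation;
acceptance decisions consume no randomness, so rejection does not bias
accepted networks. Region statistics carry percentile bootstrap CIs over
networks, and `compare_types()` bootstraps contrasts between types.

Default scale: 200 networks per type, `n` uniform on {8, 9, 10}, `q = 2`,
`p_N = 0.5`, `p_e = 0.01`. Studies of this kind are typically run at
thousands of networks per type; the default reproduces the strong
enrichments (the two-switch separation effects, the directionality
contrasts) in minutes on one CPU, while the more modest one-switch
effects sit near the noise floor at this scale and resolve cleanly when
`networks_per_type` is raised to around 1000 — the region CIs reported
with every summary make it visible which contrasts the chosen scale can
support.

## What the generator does and does not emulate

The synthetic ensembles capture the ingredients the analysis needs —
criticality, fixed in-degree logic, unbiased random wiring, exact noise
model — and nothing else. Real regulatory networks have broad and
correlated degree distributions, many more genes than the exhaustive
`2^n` analysis can hold, asynchronous and graded dynamics, and noise that
is neither uniform nor independent across genes. Passing ensembles here
therefore demonstrates properties of the model class, not of any measured
network; the myeloid-lineage application that motivated the method needs
an inferred network as input and is out of scope here.

## Numerical choices and edge cases

* Exhaustive enumeration cap `n <= 20`; dense transition-matrix cap
  `n <= 12` (raisable to 14). Both error loudly rather than degrade.
* Row sums of transition matrices are exact by construction; tests
  require 1e-12.
* MFPT solves use base LAPACK (`solve()`); a singular restricted system
  (impossible for `p_e` in (0,1)) is reported as unreachability.
* Series truncation: tail mass < 1e-9 or `10^5` terms, with the tail
  reported and a warning if the tolerance is not met.
* Ties in pair orientation keep the `(i, j)` direction and set a flag;
  classification happens after orientation, so labels are invariant to
  the order a pair is supplied in.
* Zero-in-degree nodes (constants) are legal networks; `q = 1` bias
  requests warn as described above.
* Degenerate correlation inputs (fewer than 3 points, zero variance)
  error instead of returning `NA`.

## Limitations

Exact Markov analysis is exponential in `n`; the package is honest about
this (hard caps) rather than approximate. Asynchronous updating,
per-gene noise rates, probabilistic update functions and stationary
distribution analysis are out of scope. The directional/separate
boundaries are parameters, not estimates; conclusions about region
enrichment are conditional on the chosen `p_e` and thresholds, which is
why every output records them.
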