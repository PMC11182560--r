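---
title: "The division-decision model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The division-decision model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divdec)
```

## The model

A division-decision system grows a one-dimensional tissue from a single
cell.  Every cell carries the same genome: two signed-ternary matrices
over the `n` genes.  `w_intra[p, q]` is the regulation of gene `p` by
gene `q` within a cell; `w_inter[p, q]` the regulation of gene `p` by
gene `q` expressed in a contacting neighbour, applied identically to the
left and right neighbour (there is no way to encode left/right asymmetry,
a deliberate symmetry of the model).  Gene states are binary.  One
*decision* step updates all genes of all cells synchronously from the
previous snapshot (a Markov step):

- compute `h = sum_q w_intra[p, q] g_i^q + sum_{k ~ i} sum_q w_inter[p, q] g_k^q`
- the new state is 1 if `h > 0`, 0 if `h < 0`, and unchanged on a tie.

Boundary cells simply have fewer summation terms; there are no phantom
neighbours.  Under the `biased_plus_one` rule variant the threshold is
applied to `h + 1`: the verbal description of that variant ("the sum plus
one") fixes the shift but not the tie semantics, so the variant is
isolated behind `rule_variant` and uses the same tie-holding convention.

Writing the tissue as the m-by-n matrix `S` and the tridiagonal contact
matrix as `C`, the per-cell input of a decision is the concatenated
matrix `[S, C.S]` — each row is a cell's own states plus the per-gene
sums over its neighbours.  After `updates_per_generation` decisions
(default 20, enough for every screened network to settle), all cells
divide at once and both daughters inherit the mother's state, so the
state matrix duplicates row-wise.  One daughter keeps the mother's
position and the sibling takes a random side (outward at the
boundaries); since daughters are state-identical, that randomness can
only permute *lineage labels*, never states — a property the test suite
asserts by comparing state trajectories across seeds.

## Information measures

Positional information is the mutual information between cell position
and composite cell state, `H(state) - H(state | position)`, in bits,
with uniform position weights and plug-in (maximum-likelihood) entropy
estimates — no bias correction, and none is implied by the model.  For a
single deterministic tissue the conditional term is zero and PI is just
the entropy of the state frequencies.  Potential information is the
entropy of the distinct rows of `[S, C.S]`: the information a decision
*could* convert into state differences.  Because cells with identical
concatenated rows must update identically, the PI reached one update
later can never exceed the potential information before it — an
inequality the tests check along every canonical trajectory.

Displayed step conventions: development patterns are shown with a fixed
number of steps per generation (the post-division snapshot plus the
settling updates).  The single-gene pattern settles in three displayed
steps per generation, so its information leap lands at displayed step 8;
the two-gene pattern uses four and leaps at steps 10 and 14.

## Screens and derived networks

The screens enumerate all `3^(2n^2)` networks (9 single-gene, 6561
two-gene) in a canonical base-3 id order, simulate five generations from
each initial state, and record the maximal PI along with whether it was
attained at a within-generation fixed point ("stable"); the headline
counts refer to stable maxima.  The inner loop exits a generation early
at a fixed point or a period-2 oscillation (the remainder of the window
is then determined by parity), which changes nothing about the recorded
dynamics.

The named networks beyond O1/T1/T1' are derived constants frozen from
these screens: T2–T4 are the lower-id members of the three gene-swap
pairs reaching 2.0 bit under the biased rule; T5 is the lower-id member
of the pair producing four distinct blocks in the fixed-boundary-cell
model.  The fixed-cell variant prepends an immutable cell that signals
but neither updates nor divides.  For its stripe statistics, a pattern
counts as k-block when the *dividing* cells partition into k contiguous
blocks of k distinct states; the fixed cell anchors the pattern but is
not part of it.  Plain maximal-run counting (`stripe_count()`) is also
exposed and is what the run-length examples use.

In the motif analysis, lateral inhibition (direct: a negative diagonal
`w_inter` entry; indirect: a cross-membrane activation followed by an
intracellular edge with net negative sign on the original gene)
predominates in every group of networks exceeding 1 bit, and is
universal in the 2.0-bit group.  It is predominance, not exclusivity:
the exact enumeration finds a small minority (~8%) of 1.5-bit networks
with no lateral-inhibition motif.  Correlations between motif ratio and
group PI are Pearson, computed across groups; only their signs are
asserted.

## Attractors and the division funnel

At fixed cell count the synchronous dynamics form a functional graph
over `(2^n)^m` states, built here in one vectorized pass and iterated by
map-doubling; memoization and naive iteration provably agree (the
two-cell report is checked against a literal 16-state enumeration).
States in period->1 cycles belong to no basin and are reported as cycle
mass; basins plus cycle mass partition the state space exactly, and for
T1 at m = 2, 4, 8 the cycle mass is zero.  The growing system's settled
state at each generation is looked up in the fixed-size report
(`trajectory_basin()`): the 4-cell pattern sits in a basin of 11 of 256
states and the 8-cell pattern in 71 of 65,536 — division funnels the
system into states far too rare to reach from random initial conditions.
Note that the basin-information trade-off is an upper-tail property (the
maximal-information states never hold the largest basins); the global
rank correlation over all fixed points is actually slightly positive,
because many low-information states also have tiny basins.

## Robustness

Two perturbations are modelled, each run to the 8-cell stage with
`L = 7` updates per generation by default.  *Update noise*: after each
synchronous update every cell is corrupted with probability `p` (its
gene vector resampled uniformly among wrong vectors; a per-gene flip
variant was also examined and orders the networks the same way).
*Asynchronous division*: updates stay globally synchronous but each
newborn cell draws its own cycle length from a rounded normal
(mean `L`, sd `sigma`, floored at one update) and divides on its own
clock; the run ends at the nominal developmental horizon
`generations * L`, the step at which the synchronous reference ends.
Ending at the common horizon is what gives longer cycles their buffering
effect — lagging lineages get proportionally more slack — and makes
`sigma = 0` collapse exactly onto the synchronous run.  Accuracy is the
fraction of replicates whose final tissue equals the noise-free standard
pattern exactly, with a Wilson 95% interval.  Monte-Carlo sizes in the
tests (300–500 replicates) are chosen so the asserted orderings clear
their Monte-Carlo error.

## The continuous counterpart

Each nonzero Boolean edge maps to a Hill term (activator
`x^h/(K^h + x^h)`, inhibitor `K^h/(K^h + x^h)`) on the cell's own levels
(intracellular edges) or the summed neighbour levels (intercellular
edges); per gene the terms combine through an AND gate (product), an OR
gate (normalized sum), or `AUTO_OR` (intracellular product averaged with
intercellular product — a self-maintenance branch in parallel with a
signalling branch).  Production and degradation are scaled to one.  The
default thresholds come from the module's own parameter scan: `K = 0.4`
for intracellular terms (a sizable re-ignition barrier for bistable
self-activation), `1.2` for same-gene intercellular terms (between one
and two saturated neighbour levels — low enough that two neighbours
inhibit, high enough that adjacent ON pairs at the 8-cell stage remain
dynamically stable; below ~1.0 the symmetric pair becomes a saddle and
every generation-4 pattern is destroyed by arbitrarily small noise), and
`0.5` for cross-gene intercellular terms (within reach of a single
neighbour).  Hill coefficient 4 throughout.  In this regime the
thresholded steady states (ON = above the midpoint of each gene's
attained steady range) coincide with the Boolean fixed points at
generation 3 for O1 (AND and OR) and O2, and generation 4 for T1 (gene B
through AND or OR).  O2 renders the biased rule's `+1` as constitutive
production shaped only by lateral inhibition.

T6 (T1 plus intracellular self-activation of B) uses the `AUTO_OR` gate
for B with its switch threshold at 0.25 — below the gate's halved
production ceiling, which is what makes the self-maintenance branch
bistable at all.  Its generation-4 pattern keeps B levels at four
distinct values (state memory), and that memory is exactly what costs
noise resistance: a perturbation that pushes a cell's B across the
switch stays, so T6's resistance score falls below T1's, whose B always
relaxes back.

Noise resistance `lambda` is the largest amplitude of i.i.d. uniform
`[-lambda, lambda]` concentration perturbations (clamped at zero) whose
relaxations retain the thresholded pattern in at least 95% of 200 trials
(fewer in the tests), found by bisection.  The retention criterion is
this package's operational definition — the score is defined graphically
in the source literature — so only *orderings* (AND above OR for O1,
T1 above T6, generation 3 above generation 4) are treated as meaningful,
never the numeric values.

## The C. elegans module

Embryo snapshots carry named cells, discrete state labels (from
booleanized expression; a state is named after the first cell entering
it) and a general, unordered contact graph, so potential information
uses per-cell classes of (own state, multiset of neighbour states) — the
contact-graph generalization of the concatenated matrix.  The built-in
4-cell and 12-cell snapshots are constructed in code from the in-text
account of those stages (they are working fixtures, not the full
supplementary tables, which ship as spreadsheets outside this package;
`load_embryo_tables()` accepts them as TSV/CSV with a configurable
column schema).  At the 4-cell stage the three states give 1.5 bit of
positional information while the contact graph (P2 touching ABp but not
ABa) already distinguishes all four cells — 2.0 bit of potential
information that the Notch-Delta event converts into 2.0 bit of
positional information.  The 12-cell rules show the lineage component:
ABarp (inheriting "aba") responds to C contact while ABpra (inheriting
"ab", same contact) does not.

## Problem sizes and limitations

Everything the tests and the reproduction script run is exact and
desk-scale: the full 6561-network screens take seconds to a couple of
minutes, the 65,536-state basin enumeration a few seconds, and the
Monte-Carlo and ODE checks use a few hundred replicates or trials.  The
synthetic dynamics emulate the model's own study conditions, not data:
passing tests show the implementation reproduces the model's exact
combinatorial structure, not that real tissues obey it.  Known
limitations are the model's own: one spatial dimension, contact-only
signalling, state-independent division timing, and a continuous module
whose equations are this package's standard-Hill reconstruction with
scan-chosen defaults rather than a published parameter set.
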