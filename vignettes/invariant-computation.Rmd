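---
title: "Computing Petri-net invariants, siphons and traps by constraint solving"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing Petri-net invariants, siphons and traps by constraint solving}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrinv)
```

## The model

A reaction system is read as a place/transition Petri net: species are
places, reactions are transitions, and a transition `t` carries two
weighted multisets of places — the stoichiometry of its reactants
(`pre`, written `L_t`) and of its products (`post`, `R_t`).  The
incidence matrix `I` has entry `(t, j) = R_t(j) - L_t(j)`.  A state is a
marking (token counts per place, or molecule counts per species);
firing a transition removes the `pre` weights and adds the `post`
weights.

The structural objects this package computes are:

* **P-invariant**: a vector `V` of naturals with `V^T I = 0`,
  equivalently `V·L_t = V·R_t` for every transition.  The `V`-weighted
  token sum is constant under any firing — for the ODE semantics of the
  same network, a conservation law (a conserved moiety) that holds
  whatever the rate laws.  Each independent law removes one free
  variable from the ODE system.
* **T-invariant**: the dual object over transitions, a multiset of
  firings that returns any marking to itself (a flux cycle).  It is
  computed as a P-invariant of the transposed net.
* **Non-decreasing / non-increasing pools**: relax the equalities to
  `V·L_t <= V·R_t` (resp. `>=`) for all `t`; the weighted sum then never
  decreases (resp. never increases) along any trajectory.  These are the
  sub/sur-invariant relaxations; because the literature's naming of the
  two directions is inconsistent, the package names them by the
  direction of the monotonicity, which is unambiguous.
* **Siphons and traps**: place sets.  In a trap, every transition that
  consumes from the set also produces into it — once marked, a trap
  stays marked.  In a siphon, every transition producing into the set
  also consumes from it — once empty, a siphon stays empty.

Only integer stoichiometry is supported.  Signalling, cell-cycle and
gene-regulation models are written with integer stoichiometry
essentially always; metabolic flux models with fractional coefficients
are out of scope (an opt-in rescaling by the l.c.m. of denominators
exists for SBML import).

## Enumeration as constraint solving

All four objects are solutions of small constraint problems over one
bounded variable per place:

* invariants: `t` linear relations over natural variables, plus
  `sum(V) > 0` to exclude the zero vector;
* siphons/traps: per transition, a boolean implication between the
  disjunction of its pre-places and the disjunction of its post-places
  (reversed for siphons), plus non-emptiness.

The engine (`fd_store()` and friends) is deliberately small: interval
domains, bounds-consistency propagation for linear constraints, a
"zero among these variables" constraint propagated when all but one
member is known non-zero, and depth-first labelling that takes
variables in declaration order and tries values in increasing order.
Bounds consistency is weaker than full arc consistency but sound;
search restores completeness, and on sums of many variables it is far
cheaper.  Implications over 0/1 variables compile to linear form
(`x_a <= sum(consequent)` per antecedent member), which the direct
constraint evaluator used by the tests accepts unchanged.

Minimality is support minimality: no reported solution's set of
non-zero entries strictly contains another solution's.  The search
loop is branch and bound:

1. find the lexicographically smallest remaining solution;
2. normalize it by the gcd of its weights and add it to the basis,
   removing any earlier basis vector with strictly larger support;
3. post a support-exclusion constraint — at least one variable of the
   new support must be zero in any later solution;
4. repeat until unsatisfiable.

Step 2's removal is needed in the numeric domain because value-wise
lexicographic order does not respect support inclusion.  In the boolean
domain it does: a proper sub-solution is pointwise smaller, hence
lexicographically smaller, and would have been found first, so
siphon/trap enumeration needs no minimality filtering at all — a
property the test suite asserts directly against brute-force subset
enumeration.

The enumeration order, and therefore every output, is deterministic:
variables follow place declaration order, values ascend, and the final
basis is sorted by (support size, support positions, weights).

### Choice of the domain bound

Minimal invariants of nets with unit weights have unit components, but
larger stoichiometries can force larger weights.  Two bound policies
exist:

* the default fixed bound **8**, roughly double the largest
  stoichiometric coefficient seen in curated biochemical models — the
  result carries `complete = FALSE` unless 8 already dominates the
  guaranteed bound below;
* `complete_bound(net)`: the product over transitions of the l.c.m. of
  each transition's coefficients.  Sufficient for completeness, but it
  grows explosively, so it is an explicit opt-in
  (`use_complete_bound = TRUE`).

The honest flag matters: with the default bound the basis is the set of
support-minimal invariants *within the bound*, which on real models has
always coincided with the full set but is not guaranteed to.

### One representative per support

For the equality relation, a minimal support carries a single ray of
solutions, and gcd-normalization picks its generator, so "one vector
per support" is canonical.  For the inequality relaxations a minimal
support can carry several gcd-normal solutions (the solution cone is
not one ray); the support-exclusion step then keeps exactly the first
one found, which is the lexicographically least solution on that
support.  Because the constraint systems are homogeneous, that
representative is itself gcd-normal.  The test oracles compute the same
canonical representative, so solver and oracle are comparable
vector-for-vector, not just support-for-support.

## Parallel places: merge, expand, or just count

Places with *identical* arc patterns (every transition touches them
with the same pre and post weights) are interchangeable in every
invariant, siphon and trap.  The classic ring benchmark
(`classic_net(x, y)`: `y` transitions in a cycle, `x` parallel places
per segment) shows why this matters: it has exactly `x^y` minimal
P-invariants, each picking one parallel place per segment.

Detection is purely syntactic — places are grouped by their full
(pre, post) incidence column — and merging replaces each group by one
representative place carrying the shared column, whose variable stands
for the plain sum of the member variables.  The merged variable's
domain is `[0, bound * group_size]`, since each member is capped at
`bound`.  After solving in the reduced space, each merged value `d` is
expanded by distributing `d` over the members (capped at `bound`):

* **strict** mode (the default) keeps support-minimal distributions —
  singletons when `d` fits one member — then filters the expanded set
  to inclusion-minimal supports, gcd-normal form, and one canonical
  vector per support.  This is the definitional contract, and the suite
  verifies set equality against the no-symmetry computation on random
  nets with engineered parallel copies.
* **paper** mode emits one non-decreasing representative per weight
  multiset (for `d = 4` over two members: `(0,4), (1,3), (2,2)`), the
  view produced by breaking the symmetry with ordering constraints
  `A1 <= A2 <= ...` instead of merging.  It can include
  support-non-minimal vectors and exists for comparison with that
  formulation.

With `compressed = TRUE` the expansion is not enumerated at all: the
number of strict-mode vectors is the product over groups of the number
of distinct minimal distribution supports, summed over the reduced
basis — `10^10` for the 10×10 ring, counted exactly in milliseconds
with the package's decimal big-integer arithmetic (machine doubles
would start rounding a few orders of magnitude later, and reports
serialize counts as strings for downstream safety).

A deliberate restriction: detection can optionally report
*proportional* groups (columns equal up to a per-place factor `k_i`),
but the computation paths never merge them.  With unequal `k_i` the
merged value `d` constrains which members can realize it — `3a + 2b = d`
has solutions whose supports depend on divisibility of `d` — so
support-minimality plus gcd-normalization in the reduced space discards
multiples of a reduced vector whose expansions differ, and solutions
are silently lost.  Merging is therefore only applied where it is
provably exact, the equal-pattern case, which is also the case that
actually occurs in biochemical models.  For T-invariant computation the
same merging acts on the transposed net, i.e. on parallel transitions
(duplicate reactions).

## Dynamic meaning, and how it is tested

Every structural claim has a token-level counterpart, and the suite
checks both routes independently of the solver:

* definitional: reported vectors satisfy `V·L_t (=, <=, >=) V·R_t`
  recomputed directly from the net; reported sets pass the direct
  `is_trap()` / `is_siphon()` checkers;
* dynamic: along random firing sequences (length 50), equality
  invariants keep their weighted sum constant, `le`-pools never
  decrease, `ge`-pools never increase, marked traps stay marked and
  empty siphons stay empty;
* exhaustive: on random nets small enough to enumerate (up to 6 places,
  bound 4 for invariants; up to 8 places for sets), the solver output
  equals brute-force enumeration reduced to minimal supports.

## What the generators emulate

`random_net(p, t, max_weight, density, seed)` draws each (transition,
place) arc independently with the given density and uniform weights,
guaranteeing every transition touches the net, and is fully reproducible
from its seed.  These nets exercise the solver hard — they are denser
and more weight-heterogeneous than curated reaction networks, which are
sparse, near-unitary and conservative — so passing the oracle tests on
them says the algorithms are correct, not that real models look like
this.  What random nets rarely produce is exact place symmetry, so the
round-trip tests add explicit parallel copies of randomly chosen places.
The curated-model shape is represented by `enzymatic_net()` (the
textbook enzyme mechanism) and `mapk_cascade()`, a synthetic
re-encoding of the scaffold-free two-site MAPK phosphorylation cascade
(22 species, 30 transitions after splitting reversible bindings) whose
7 conserved moieties — four cascade levels, three phosphatases — reduce
its ODE system from 22 to 15 free variables.  `philosophers_net()` and
`circular_trains_net()` follow one fixed standard encoding each; since
published benchmark encodings of these families vary, they are used for
property tests only, never for exact-count assertions.

## Numerical and degenerate-input choices

* Reversible reactions split into forward/backward transitions
  (`r`, `r_rev`); the backward direction adds only a redundant equality
  for P-invariants but is essential for T-invariants.
* SBML modifiers become read arcs (weight 1 on both sides): invisible
  to the incidence matrix and to invariants, visible to siphon/trap
  pre/post-set logic — an enzyme gates token flow but conserves
  nothing by itself.
* Isolated places are kept and each yields its trivial unit
  conservation law.
* Duplicate reactions are kept as distinct transitions.
* Self-loop-only constraint rows (`pre = post`) are skipped as
  tautologies; sources and sinks are legal and handled by propagation
  (a place consumed by a product-less transition can join no trap).
* Empty nets, nets without transitions, and unsatisfiable systems all
  return empty results rather than errors; an inconsistent constraint
  store is a state, not an exception.

## Problem sizes

The shipped suite runs the exhaustive-oracle comparison on 200 seeded
random nets per property (≤ 6 places and bound 4 for invariants, which
keeps the brute-force grid at `5^6` vectors), the symmetry round trip on
200 nets of up to 8 places, and 100 firing simulations of length 50.
These sizes were chosen to keep the full suite under a few minutes
while leaving the solver no room to be accidentally right: every
support, weight and set is compared exactly.

## Limitations

* Completeness under the default bound is empirical, not guaranteed;
  use `use_complete_bound = TRUE` when the guarantee matters and the
  net is small.
* Symmetry handling is global and syntactic, found once before solving;
  symmetries that only appear during search, proportional (unequal
  factor) groups, and general graph automorphisms are not exploited.
* The basis is the set of support-minimal semi-positive invariants
  within the bound — it is not claimed to generate the full invariant
  lattice.
* No kinetic information is read or used: rate laws, ODE integration
  and model reduction beyond counting free variables are out of scope.
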