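---
title: "Target control of Boolean networks via value percolation and trap spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target control of Boolean networks via value percolation and trap spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnctrl)
```

## Model and problem

A Boolean network on `n` variables is a function
`f = (f_1, ..., f_n) : {0,1}^n -> {0,1}^n`. `bnctrl` stores each coordinate
function in disjunctive normal form (DNF): a list of clauses, each clause a
set of signed literals; the empty DNF is the constant 0 and a DNF containing
an empty clause is the constant 1. The dynamics is a state transition graph
under one of three updates — synchronous (all updatable components switch),
asynchronous (one at a time; the default, as it better reflects unknown
biological time scales), or generalized asynchronous (any nonempty subset).
Attractors are the terminal strongly connected components; a subspace
(partial assignment, written with `0/1/*`) closed under the dynamics is a
trap space. Trap spaces do not depend on the update; attractors do.

The control problem: given a target subspace `P`, find all
inclusion-minimal consistent sets of node interventions (clamp a component
to a constant) and/or edge interventions (fix one input inside one rule) of
size at most `k` such that every attractor of the controlled network lies in
`P`. Membership of a candidate set is decided by value percolation, which
gives two sufficient conditions:

1. **Direct percolation**: the iterated percolation fixpoint of the full
   state space under the controlled network fixes all `P`-variables at
   their target values.
2. **Via selected trap spaces**: the fixpoint lands inside a
   *non-percolating* trap space `T` whose attractors all lie in `P`, with
   every intervention targeting a variable fixed in `T` (for edge
   interventions, the target function). These strategies preserve the
   original attractors inside `T` and remain valid if the interventions are
   released after the trap space is reached.

Both conditions are sufficient, not necessary: the returned antichain is
sound but not exhaustive with respect to the defining property, which is why
the package also ships `verify_strategy()`, a ground-truth oracle that
checks the definition directly on the explicit state transition graph of
small networks.

## Exactness choices

Constancy of a restricted function is the workhorse predicate (percolation,
trap-space tests, preprocessing). It is decided *exactly*: fixed variables
are substituted syntactically, then all `2^k` assignments of the remaining
free regulators are enumerated. Purely syntactic partial evaluation would
miss tautologies such as `x | !x` that arise after rewriting and would
corrupt percolation results. The enumeration is capped at `max_indegree`
free regulators (default 16, configurable), which comfortably covers
published biological models, whose in-degrees are small.

Trap spaces are enumerated by an exact depth-first search over partial
assignments with three choices per variable (free, 0, 1), pruning a branch
as soon as some fixed variable's restricted function is constant at the
wrong value — such a constant can never revert on a smaller subspace. The
test suite cross-checks this search against a `3^n` brute force on dozens
of random networks.

`percolate()` only accepts trap-space starts (in the search it is always
started from the full state space, which is trivially a trap space). For
arbitrary subspaces the iteration of the percolation function has no
comparable monotonicity guarantee, so such starts are refused rather than
given ad-hoc semantics.

## The search

For each witness (the target for direct percolation; each selected trap
space for the trap-space route) a candidate list is generated. Consistent
candidate subsets are then enumerated globally by increasing size; a subset
is accepted when it percolates into *any* witness whose candidate
restriction it satisfies, witnesses being tried largest-first (fewest fixed
variables, ties by rendering). Supersets of accepted sets are pruned, so
the output is the complete inclusion-minimal antichain up to `max_size`,
sorted by size then by the textual rendering of the intervention set —
identical inputs always give identical output. The empty set counts as a
candidate combination; when the uncontrolled state space already percolates
into a witness it is reported as the unique minimal strategy.

Several places needed a decision where more than one reading was plausible:

* **"Percolates to `P`"** is implemented as *the fixpoint fixes every
  `P`-variable at its target value* (it may fix more), not as strict
  equality with `P`. This matches the goal-satisfaction semantics used by
  constraint encodings of percolation control and makes the direct and
  trap-space routes uniform.
* **Equivalence of intervention sets** is defined on percolation
  *fixpoints* from the full state space. A one-step variant is also
  provided (`mode = "one_step"`), but the fixpoint version is the default:
  it is transitive and matches the long-term reading of equivalence (a
  node clamp and the matching edge intervention on a single-regulator
  component produce the same fixpoint but not always the same single
  percolation step).
* **Type 2 selection under the minimal-trap-space approximation.** When
  attractors are only known through the approximation "each minimal trap
  space contains exactly one attractor and every attractor lies in one"
  (checkable on small networks with `mts_approximation_check()`), the test
  "every attractor inside `T` lies in `P`" is decided as: every minimal
  trap space `m` contained in `T` satisfies `m` contained in `P`. Under the
  approximation, attractors are faithfully located by their minimal trap
  spaces, and a `P`-variable left free in `m` means the attractor's
  location in `P` cannot be certified, so containment correctly fails. An
  explicit attractor list always overrides this reading, and without any
  attractor source Type 2 witnesses are skipped with a warning.
* **The signed-path candidate reduction** for direct node control keeps a
  candidate `(i, c)` only if a sign-consistent walk (sign = product of edge
  signs, length 0 allowed) leads from `i` to a witness variable fixed at
  `c` (positive walk) or `1 - c` (negative walk). It is treated as
  correctness-neutral pruning: it is on by default for direct node
  candidates, never applied to edge candidates or trap-space candidates,
  can be disabled (`reduction = FALSE`), and the suite asserts the result
  set never changes when it is disabled.
* **Witness overlap in the combined method** is deliberate: a selected trap
  space equal to the target simply appears under both modes; acceptance
  records whichever witness succeeds first, and the strategy set is
  unaffected.

Consistency of mixed sets follows the priority of node over edge control:
an edge intervention may neither target the function of a clamped component
nor have a clamped component as source, no component is clamped to both
values, and no edge pair fixes the same source in the same function to both
values. These three conditions are checked pairwise, so subset enumeration
can test them incrementally.

## Preprocessing and degenerate inputs

Constant regulatory functions are percolated away before the search
(`percolate_constants()`), substituting forced values until the network is
constant-free; the removed variables form a context that is appended to all
reported witnesses and fixpoints, and the suite verifies that attractors of
the reduced network extended by the context equal those of the original. If
the target contradicts a forced constant the search warns and returns no
strategies; if the whole network collapses, the forced state either already
satisfies the target (empty strategy) or nothing can.

Edge interventions must name a syntactic regulator of the target function;
a syntactic but non-essential regulator is accepted with a warning, since
the rewriting is still well-defined. DNF rewriting deduplicates clauses
after literal removal and detects constants 0/1 by emptied DNF/clause; any
hidden tautology left behind is caught by the exact constancy check at
percolation time.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_size` (`k`) | 3 | largest number of interventions per strategy; the enumeration is exponential in it |
| `kind` | `"node"` | intervention kinds searched: node, edge, or both |
| `method` | `"combined"` | witness families: direct, trap spaces, or both |
| `update` | `"async"` | update scheme for attractor-dependent steps |
| `attractor_source` | `NULL` | attractor knowledge for Type 2 witnesses: `"stg"`, `"mts"`, an explicit list, or none |
| `max_indegree` | 16 | cap on enumerated free regulators per constancy check |
| `stg_cap` | 20 | cap on variables for explicit state-transition-graph constructions |
| `reduction` | `TRUE` | signed-path pruning of direct node candidates |

The state-transition-graph cap exists because explicit dynamics need `2^n`
states; beyond it, attractor-dependent features require a user-supplied
attractor list (or the declared minimal-trap-space approximation), exactly
as large published models are handled in practice.

## What the random generator emulates

`random_network()` draws, per variable, a regulator set of size uniform in
`1..max_indegree` and a uniformly random non-constant truth table over it
(bias adjustable via `clause_bias`), written as the DNF of its minterms.
This emulates the two features the algorithms depend on — sparse
regulation and constant-freeness — and deliberately not the degree
distributions, canalization or motif structure of curated biological
networks. Passing the randomized suites therefore demonstrates logical
correctness of enumeration, percolation and search on arbitrary sparse
networks, not biological realism; the bundled hand-sized examples and the
(externally supplied) case-study models cover behaviour on
biologically-shaped inputs.

The randomized suites run on 50 networks with 4–8 variables and in-degree
at most 3, sizes at which every claim can be checked against an
independent brute-force oracle (full `3^n` subspace scans, reachability
closure over all `2^n` states) within seconds per network.

## Known limitations

* The subset enumeration is exact but exponential; it is intended for desk
  scale (dozens of variables with small `k` for node control). No
  declarative-solver backend is bundled; the search layer is written so one
  could be plugged in, provided it reproduces the identical antichain.
* Attractor computation is explicit (terminal SCCs of the full graph);
  there is no symbolic/BDD engine, which is why large networks must supply
  attractors or rely on the minimal-trap-space approximation.
* Only inclusion-minimality is supported as the optimality notion;
  cost-weighted objectives, temporary/timed interventions and sequential
  schedules are out of scope.
* The bnet dialect covers `!`, `&`, `|`, parentheses and the constants
  0/1; SBML-qual or GINsim import is not provided.
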