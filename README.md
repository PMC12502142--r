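# bnctrl

Target control of Boolean networks via value percolation and trap spaces.

## The problem

Boolean networks are a standard qualitative model of gene regulatory and
signalling systems: each component is a binary variable and each variable's
regulatory rule is a logical function of its inputs. The long-term behaviour
of the model is captured by its attractors — the terminal strongly connected
components of the state transition graph — which correspond to cell fates,
phenotypes or oscillatory programs. *Target control* asks for a small set of
interventions that guarantees that **every** attractor of the perturbed
system lies inside a target subspace `P` (e.g. `Apoptosis = 1`), whatever
the initial state.

`bnctrl` implements and combines two sufficient conditions for an
intervention set `C` to be a control strategy:

* **Direct percolation.** The percolation function `F(f)` maps a subspace
  `S` to the smallest subspace containing its image `f(S)`. If the full
  state space percolates into `P` under the controlled network `f^C`
  (i.e. the iterated fixpoint of `F(f^C)` fixes every `P`-variable at its
  target value), then `C` is a control strategy for `P`.
* **Percolation via selected trap spaces.** A trap space is a subspace
  closed under the dynamics; a *selected* trap space contains only
  attractors that lie in `P`. If the state space percolates into a selected
  trap space `T` under `f^C`, with all interventions targeting variables
  fixed in `T`, then `C` is a control strategy for `P` — and, unlike direct
  percolation, it cannot create new attractors, so the interventions may be
  released once the trap space is reached. This route finds strictly more
  strategies than direct percolation alone.

Two kinds of intervention are supported, separately or mixed: **node
interventions** `(i, c)` clamp a component and its rule to a constant
(knockout / constitutive activation), and **edge interventions** `(i, j, c)`
fix the value of input `i` only inside the rule of `j` (e.g. a mutation that
blocks one specific protein–protein interaction). Mixed sets must satisfy
three consistency conditions (node control takes priority over edge
control). The search enumerates consistent candidate subsets by increasing
size, prunes supersets of accepted sets, and returns the complete
inclusion-minimal antichain of control strategies up to a size limit, each
annotated with its witness subspace and percolation fixpoint.

For whom: modellers working with logical models of regulatory networks
(bnet format, as used by the PyBoolNet model repository) who want exact,
reproducible enumeration of minimal node/edge intervention sets on desk-size
networks, with a ground-truth attractor oracle for validation on small ones.

## Worked example

A three-variable bistable network with rules
`f = (x2 | x3, x2 & !x3 | !x1 & !x3, x2 & x3 | x1 & x3)`:

```r
library(bnctrl)
net <- example_networks()$bistable3

trap_spaces(net)$subspace
#> [1] "***" "**0" "*10" "1*1" "101" "110"

unlist(attractors(net, "async")$states)
#> [1] "101" "110"
```

The network has six trap spaces and two steady states, `110` and `101`.
Targeting the steady state `110` with node interventions:

```r
control_strategies(net, "110", method = "combined", kind = "node",
                   max_size = 2, attractor_source = "stg")
#> # A tibble: 1 × 6
#>   strategy  size method         witness fixpoint interventions
#>   <chr>    <int> <chr>          <chr>   <chr>    <list>
#> 1 x3=0         1 via_trap_space **0     **0      <intrvntn_>
```

The single minimal strategy clamps `x3` to 0: the state space percolates to
the trap space `**0`, which contains only the attractor `110`. Direct
percolation alone misses it and needs two interventions:

```r
control_strategies(net, "110", method = "direct", kind = "node", max_size = 2)
#> # A tibble: 1 × 6
#>   strategy   size method witness fixpoint interventions
#>   <chr>     <int> <chr>  <chr>   <chr>    <list>
#> 1 x2=1,x3=0     2 direct 110     110      <intrvntn_>
```

Every returned strategy can be validated against the exact dynamics on
small networks:

```r
verify_strategy(net, intervention_set(c(x3 = 0)), "110")
#> [1] TRUE
```

A command-line wrapper for batch use is installed at
`system.file("cli", "bnctrl", package = "bnctrl")` with subcommands `find`,
`trapspaces`, `attractors` and `verify`.

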