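---
title: "Canalization and control in Boolean network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canalization and control in Boolean network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bncana)
library(igraph)
```

## The model

A Boolean network is a set of `N` binary automata. Each automaton `x_i`
carries a look-up table (LUT): a truth table over its `k_i` inputs whose
`2^k` rows give the automaton's next state for every input combination. All
automata update *synchronously*, so the network defines a deterministic map
on the `2^N` binary configurations. Boolean networks are the workhorse
coarse-grained model of gene regulation and biochemical signaling: nodes are
genes or proteins, "on/off" abstracts expression, and the wiring encodes the
regulatory logic.

Two conventions fix all encodings in this package:

* **LUT rows.** Rows are ordered by the binary value of the input states with
  the *first listed input as the most significant bit*: row 1 is all-zeros,
  row `2^k` is all-ones.
* **Configurations.** A network configuration is the integer whose binary
  expansion lists the node states in declaration order, first node = MSB.
  `encode_config()` / `decode_config()` convert between the two forms.

Networks can be built in code from `lookup_table()` objects or read from
`.cnet` text files (`parse_cnet()` / `write_cnet()`), a plain dialect with a
`.v` node-count line, optional `.l` labels, one `.n` block per node, and
truth-table rows that may compress with the `-` wildcard. Several published
regulatory networks ship in `inst/extdata` (see `example_manifest()`),
including the *Arabidopsis thaliana* floral organ determination network.

## Canalization as logical redundancy

A LUT is *canalizing* when some inputs can determine the transition on their
own, making the remaining inputs redundant in those contexts. We quantify
this by redescribing the LUT as **wildcard schemata**: patterns over
`{0, 1, #}` in which `#` ("don't care") marks inputs whose state is
irrelevant given the rest. The schemata for an output value are exactly the
*prime implicants* of that value, computed with the Quine–McCluskey
algorithm — and we keep **all** prime implicants, not a minimum cover,
because the redundancy measures are defined over the complete redescription.

```{r}
tfl1 <- load_example("thaliana")$nodes[["TFL1"]]
prime_implicants(tfl1, 1)
prime_implicants(tfl1, 0)
```

The TFL1 automaton has four inputs but its ON transition is fixed by just
three conditions, and each OFF transition by a single condition — a strongly
canalizing function.

**Two-symbol schemata** (`two_symbol_schemata()`) add a second kind of
redundancy: *position-free* groups of inputs whose symbols may permute
without changing the transition (the two inputs of XOR, or all three inputs
of a majority rule). Groups are grown by greedy pairwise merging and every
merge is validated by exhaustively expanding the joint permutation closure of
the proposed group set, so a returned schema is self-checking: every
arrangement it denotes is a valid wildcard schema.

### The measures

`canalization()` summarizes a LUT by three numbers in `[0, k]`:

* **input redundancy `k_r`** — the mean, over LUT rows, of the number of `#`
  symbols in the schemata redescribing that row;
* **effective connectivity `k_e = k − k_r`** — how many inputs the automaton
  *effectively* needs;
* **input symmetry `k_s`** — the analogous mean count of position-free
  symbols.

Two conventions are options, not hard-coded:

* `norm = "max"` (default) scores each row by the *most redundant* schema
  covering it; `norm = "mean"` averages over all covering schemata. Under
  the mean tally the per-input measures add up exactly: `k_r = sum(r_j)`,
  so the per-input effectiveness decomposes `k_e` — the property the
  effective graph relies on.
* `allow_constant_groups` (default `TRUE`) admits position-free groups whose
  symbols are all identical (their permutations are trivially valid). Under
  this convention fully symmetric rules such as majority report
  `k_s = k`; switching it off counts only "visible" symbol exchanges.

The per-input decomposition is returned as `per_input`: redundancy `r_j`
(how often input `j` is a `#` in the covering schemata), effectiveness
`e_j = 1 − r_j`, and symmetry `s_j`.

```{r}
canalization(tfl1)
canalization(tfl1, norm = "mean")$per_input
```

AP2 has `r_j = 1`: it never decides a TFL1 transition.

## Canalization maps

Two graph views make the redescription tangible:

* The **effective graph** (`effective_graph()`) re-weights each regulatory
  edge `j → i` by the effectiveness `e_j` of input `j` in automaton `i`
  (mean tally). Zero-weight edges — inputs that are wired but never decisive,
  like AP2 → TFL1 above — are pruned by default.
* The **canalizing map** (`canalizing_map()`) unfolds a LUT's schemata into a
  McCulloch–Pitts-style threshold network: *s-units* for each node-state
  literal and *t-units* for each multi-condition schema, whose threshold
  equals its number of input conditions. `dynamics_canalizing_map()` takes
  the union over all automata (sharing the `2N` s-units), giving a parsimonious
  circuit of the network's entire dynamical logic; `cm_restrict()` slices one
  automaton back out.

Both structures export deterministically to DOT and GraphML via
`export_graph()`.

## Dynamics and attractors

`build_stg()` materializes the state-transition graph (STG) over all `2^N`
configurations (out-degree exactly 1 under synchronous update).
`find_attractors()` enumerates the attractors — fixed points and limit
cycles — by two independent complete methods:

* `method = "exhaustive"` walks every trajectory, also returning exact basin
  sizes;
* `method = "trajectory"` composes the successor map with itself (pointer
  doubling, `N` squarings reach horizon `2^N`), so every configuration lands
  on its cycle; the distinct landing states are exactly the attractor states.
  Faster in practice, no basins.

Both are exponential in `N` by nature; the `limit` argument (default
`N ≤ 20`) refuses anything larger. The test suite cross-checks the two
methods on random `N = 8` networks.

```{r}
th <- load_example("thaliana")
atts <- find_attractors(th)
length(atts)
```

The floral network's `2^15` configurations collapse onto exactly 10 fixed
points, matching the cell types of the flower model.

## Control

A *driver set* `D` is a set of nodes subject to instantaneous bit-flip
interventions. The **controlled STG** (`build_cstg()`) adds, from every
configuration, one controlled edge to each of the `2^|D| − 1` configurations
differing on a non-empty subset of `D`; the flip is a standalone transition
(natural dynamics resume from the flipped configuration along the existing
natural edges, they are not fused with a simultaneous update step).

From the CSTG:

* `reachability_fractions()` gives, per configuration, the fraction of the
  `2^N − 1` *other* configurations reachable from it (computed on the
  strongly-connected-component condensation, so cost is near-linear in the
  CSTG size);
* `control_measures()` averages this into the **mean reachable fraction**
  `Rbar` and subtracts the uncontrolled baseline to get the **mean
  controlled fraction** `Cbar` (`Cbar <= Rbar` always; `Rbar = 1` exactly
  when the CSTG is strongly connected — full controllability);
* `build_cag()` / `attractor_control()` lift reachability to the attractor
  level: the **controlled attractor graph** has an edge `k → g` when some
  configuration of attractor `k` reaches attractor `g` in the CSTG (any
  cycle member is equivalent, and reaching a basin implies reaching its
  cycle, since natural edges flow inward), and `Abar` is the mean fraction
  of the *other* attractors reachable, defined as 1 when the network has a
  single attractor so that full control always scores 1;
* `driver_sweep()` tabulates these for every driver subset up to a size cap
  (default 2, hard cap 4 — the sweep is combinatorial).

```{r}
net <- random_nk(4, 2, seed = 11)
control_measures(net, drivers = "x1")
driver_sweep(net, max_size = 1)
```

Two structure-only driver-set estimators complement the exact measures:

* `sc_driver_set()` — structural controllability: unmatched nodes of a
  maximum matching on the bipartite out/in representation of the interaction
  graph (self-inputs count as matchable); a perfect matching returns the
  first-declared node.
* `mds_driver_set()` — a minimum dominating set, exact (branch and bound)
  up to `exact_limit = 25` nodes, greedy beyond that (flagged by the
  `exact` attribute); ties break lexicographically so results are
  deterministic.

These are known to disagree with the exact dynamical measures on strongly
canalizing biological networks — comparing them is the point of computing
both.

## Random ensembles

`random_nk(N, K, bias, seed)` draws Kauffman NK networks: every node gets
`K` distinct inputs uniformly at random and an independent Bernoulli(`bias`)
output column. This emulates the classic null ensemble against which the
canalization of real regulatory logic is judged — real LUTs are *far* more
redundant than bias-matched random ones. The generator restores the caller's
RNG state when a seed is given.

## Numerical and scale choices

All measures are small rational numbers (integer counts over `2^k` or
`2^N − 1` denominators) evaluated in double precision; the representation
error is ~1e-16, and the suite asserts the decomposition identities to
1e-12. Exhaustive machinery is guarded: state-space work refuses `N > 20`
by default, two-symbol closure refuses `k > 16`, driver sweeps cap at subset
size 4, and the brute-force oracles used in the tests carry their own tighter
caps (`k ≤ 6`, `N ≤ 12`, …). Property tests run on random LUTs with
`k ≤ 4` and networks with `N ≤ 8` — sizes at which the independent oracles
stay fast while still exercising every code path.
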