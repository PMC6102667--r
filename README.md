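# bncana

Canalization and control in Boolean network models of biochemical
regulation.

Boolean networks model genes and proteins as binary automata updated by
look-up tables (LUTs) over their regulatory inputs. Most biological logic is
*canalizing*: a few input conditions decide a transition and the remaining
inputs are redundant. `bncana` quantifies that redundancy, redraws the
network in terms of it, and measures how it constrains the network's
controllability:

* **Schemata redescription** — `prime_implicants()` compresses a LUT into
  its wildcard schemata (all Quine–McCluskey prime implicants, `#` = "don't
  care"); `two_symbol_schemata()` adds position-free groups of permutable
  inputs, each validated by exhaustive permutation closure.
* **Canalization measures** — `canalization()` returns input redundancy
  `k_r`, effective connectivity `k_e = k − k_r` and input symmetry `k_s`,
  plus the per-input redundancy/effectiveness/symmetry decomposition.
* **Canalization maps** — `effective_graph()` (regulatory edges weighted by
  input effectiveness, never-decisive edges pruned), `canalizing_map()` and
  `dynamics_canalizing_map()` (threshold-network unfolding of the schemata);
  deterministic DOT/GraphML export via `export_graph()`.
* **Dynamics** — `build_stg()`, `find_attractors()` (two independent
  complete enumeration methods, exact basin sizes), `random_nk()` Kauffman
  ensembles, and a plain-text `.cnet` reader/writer with packaged classic
  models (`load_example()`), including the *Arabidopsis thaliana* floral
  organ determination network.
* **Control** — `build_cstg()` (state-transition graph extended with
  bit-flip driver interventions), `control_measures()` (mean reachable and
  controlled configuration fractions), `build_cag()` / `attractor_control()`
  (attractor-level reachability), `driver_sweep()`, and the structure-only
  estimators `sc_driver_set()` (maximum matching) and `mds_driver_set()`
  (minimum dominating set).

## A worked example

The floral regulator TFL1 has four inputs but almost no effective logic:

```r
library(bncana)

th <- load_example("thaliana")
tfl1 <- th$nodes[["TFL1"]]

prime_implicants(tfl1, 1)
#> 1 wildcard schema(ta)
#> schema 010# -> 1          # AP1=0, EMF1=1, LFY=0; AP2 is irrelevant

canalization(tfl1)
#> Canalization of 'TFL1' (k = 4, norm = max)
#>   input redundancy   k_r = 2.75
#>   effective inputs   k_e = 1.25
#>   input symmetry     k_s = 3.625
#>   per input:
#>  input      r      e      s
#>    AP1 0.5833 0.4167 1.0000
#>   EMF1 0.5833 0.4167 0.6042
#>    LFY 0.5833 0.4167 0.7917
#>    AP2 1.0000 0.0000 0.8750
```

AP2 never decides a TFL1 transition (`e = 0`), so `effective_graph(th)`
prunes the AP2 → TFL1 edge. The network's `2^15` configurations collapse
onto exactly ten fixed-point attractors, the cell types of the flower model:

```r
length(find_attractors(th))
#> [1] 10
```

Driver-based control of a small random network:

```r
net <- random_nk(4, 2, seed = 11)
control_measures(net, drivers = "x1")
#> Control report for drivers {x1}
#>   mean reachable fraction   R = 0.55
#>   mean controlled fraction  C = 0.3292

sc_driver_set(th)   # structural controllability says 3 drivers suffice...
#> [1] "LUG" "CLF" "SEP"
mds_driver_set(th)  # ...minimum dominating set says 6
#> [1] "UFO"  "EMF1" "LUG"  "CLF"  "TFL1" "SEP"
```

The exact dynamical measures (`Rbar`, `Abar`) routinely contradict both
structure-only estimates on canalizing networks — computing that gap is the
package's purpose.

See the vignette (`vignettes/canalization-and-control.Rmd`) for the model
conventions, the measure definitions and every design decision.

## Command line

A thin CLI over the same functions ships in `inst/cli/bncana`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "bncana", package = "bncana"))')
NET=$(Rscript -e 'cat(system.file("extdata", "thaliana.cnet", package = "bncana"))')
"$CLI" attractors "$NET"
"$CLI" canalization "$NET" --norm mean --json
"$CLI" effective-graph "$NET" -o thaliana.graphml
"$CLI" control "$NET" --drivers LFY,AP1
"$CLI" generate --n 10 --k 2 --bias 0.5 --seed 42 -o random.cnet
```

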