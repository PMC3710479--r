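# rxnbool

Bipartite Boolean modelling of reaction-contingency networks in R.

## The problem

Signal-transduction networks are combinatorially complex: each protein can
carry several modifications and bindings at once, so quantitative models of
whole pathways need enormous numbers of specific states and parameters.
Classical Boolean models avoid that cost by giving each component a single
on/off variable — but that *decontextualises* activation: a kinase switched
on by two different upstream signals activates **all** of its downstream
targets, so crosstalk and signal specificity cannot be represented.

`rxnbool` implements a bipartite alternative for networks written in the
reaction-contingency style: the network is a list of *elemental reactions*
(`Ssk1_ppi_Ssk2`, `Hog1_P+_Hot1`, …), the *elemental states* they produce
or consume (bonds `Ssk1--Ssk2`, modifications `Hog1-{P}`), and
*contingencies* — contextual constraints saying which states are required
(`!`), inhibiting (`x`), or quantitative modifiers (`K+`/`K-`) of each
reaction. The executable Boolean model keeps both node classes:

* **reactions** are functions of states via contingencies (plus presence of
  their components):

  `Hog1_P+_Hot1(t+1) = Hog1(t) ∧ Hot1(t) ∧ Hog1-{P}(t)`
  `Ssk1_ppi_Ssk2(t+1) = Ssk1(t) ∧ Ssk2(t) ∧ ¬Ssk1-{P}(t)`

* **states** are functions of the reactions that produce or consume them.
  Products of *reversible* reactions decay when the reaction goes off;
  products of *irreversible* reactions latch until a consumer removes them:

  `Sln1-{P}(t+1) = Sln1_AP_Sln1(t) ∨ Sln1-{P}(t) ∧ ¬Sln1_PT_Ypd1(t)`
  `Ssk1--Ssk2(t+1) = Ssk1_ppi_Ssk2(t)`

Components and inputs are constant; outputs behave like states. The mapping
from network definition to model is deterministic — one network, one Boolean
model, no parameters. Because a state like `Ste5--Ste11` is distinct from
`Ste11-{P}`, a signal's *context* travels with it, and pathways sharing
kinases keep their outputs apart where a component-level model merges them.
The package also generates that component-level "classical" collapse
(`build_classical()`) precisely to demonstrate the difference.

## What's in the package

* `parse_quick()`, `load_tabular()`, `write_quick()`, `write_tabular()` —
  text and tabular network input/output; user-extensible reaction-type
  registry (`reaction_types()`, `read_registry()`).
* `validate_model()` — diagnostics (unproduced effectors, unopposed
  phosphorylations, dangling Boolean nodes, …).
* `build_bipartite()`, `build_classical()` — model generation;
  `tidy()`/`glance()` on everything.
* `run_sync()` — synchronous simulation with perturbation schedules
  (`perturbations()`), clamping, and point/cycle attractor detection;
  `run_async()` — random-order asynchronous ensembles with mean-activity
  output.
* `enumerate_full()`, `reachable()` — state-transition graphs, attractors
  and basin sizes; GraphML/DOT export.
* `trajectory_heatmap()`, `autoplot()` — clustered binary time-course heat
  maps and activity line plots; `write_bnet()` — BoolNet-style export with
  an id alias table; `export_regulatory_graph()`.
* Fixtures: `simplified_hog()` (two-module osmostress pathway with
  feedback), `toy_crosstalk()` (pheromone/osmostress crosstalk),
  `random_model()`; repair utility `add_reverse_reactions()` and the
  case-study loader `load_mapk()`.
* A thin command-line wrapper in `inst/cli/rxnbool`
  (`validate`, `export`, `simulate`, `statespace`, `fixtures`, `repair`).

## Worked example

```r
library(rxnbool)

m <- parse_quick(c(
  "Sln1_AP_Sln1; ! [Turgor]",
  "Sln1_PT_Ypd1; ! Sln1-{P}",
  "Ssk1_ppi_Ssk2; x Ssk1-{P}"))
tidy(build_bipartite(m))
#>    variable      role      rule                                         constant
#>  6 Sln1_AP_Sln1  reaction  Sln1 & [Turgor]                              FALSE
#>  7 Sln1_PT_Ypd1  reaction  Sln1 & Ypd1 & Sln1-{P}                       FALSE
#>  8 Ssk1_ppi_Ssk2 reaction  Ssk1 & Ssk2 & ! Ssk1-{P}                     FALSE
#>  9 Sln1-{P}      state     Sln1 & (Sln1_AP_Sln1 | Sln1-{P} & ! Sln1_PT… FALSE
#> 10 Ypd1-{P}      state     Ypd1 & (Sln1_PT_Ypd1 | Ypd1-{P})             FALSE
#> 11 Ssk1--Ssk2    state     Ssk1 & Ssk2 & Ssk1_ppi_Ssk2                  FALSE
```

Each row is one update rule (time `t` on the right, `t+1` on the left).
The autophosphorylation fires only under turgor; the phosphotransfer
requires *and consumes* `Sln1-{P}`; the dimer tracks its reversible
producer; `Ssk1-{P}` here has no producer, so it is frozen and flagged by
`validate_model()`.

Simulating the full simplified osmostress model:

```r
bh <- build_bipartite(simplified_hog())
tr <- run_sync(bh, default_init(bh, "[Turgor]"),
               perturbations(0, "[Turgor]", TRUE, clamp = TRUE))
tr
#> <trajectory> 16 steps, 28 variables; point attractor (period 1) entered at t = 15
at_attractor(tr)[c("Sln1_AP_Sln1", "Ssk1-{P}", "Ssk1_ppi_Ssk2", "Hog1_P+_Hot1")]
#>  Sln1_AP_Sln1      Ssk1-{P} Ssk1_ppi_Ssk2  Hog1_P+_Hot1
#>          TRUE          TRUE         FALSE         FALSE
```

With turgor clamped on, the phosphorelay runs, phosphorylated Ssk1 blocks
the Ssk1–Ssk2 interaction, and the MAP kinase module stays silent — the
high-turgor steady state. Released, the output-to-turgor feedback turns the
system into a relaxation oscillator:

```r
run_sync(bh)
#> <trajectory> 33 steps, 28 variables; cycle attractor (period 32) entered at t = 1
```

`autoplot(tr)` draws the clustered yellow/blue time-course heat map;
`glance(enumerate_full(...))` tabulates attractors and basin sizes.

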