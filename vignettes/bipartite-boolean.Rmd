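---
title: "Bipartite Boolean models from reaction-contingency networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bipartite Boolean models from reaction-contingency networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnbool)
```

## The modelling idea

A reaction-contingency network describes signalling at the level of
*elemental reactions* — single biochemical events between at most two
components, such as a binding (`Ssk1_ppi_Ssk2`) or a phosphorylation
(`Hog1_P+_Hot1`) — and the *elemental states* those events create or
remove: bonds (`Ssk1--Ssk2`) and modifications (`Hog1-{P}`). Elemental
states are not mutually exclusive; each is the set of all specific
molecular configurations sharing one property. *Contingencies* add the
regulatory layer: a state (or input, or a Boolean combination) can be
required for (`!`), inhibiting (`x`), or a quantitative modifier
(`K+`/`K-`) of a reaction.

`rxnbool` turns such a network into an executable Boolean model that keeps
the two node classes separate, mirroring the bipartite regulatory graph.
This avoids the decontextualisation of component-level ("classical")
Boolean models: because `Ste5--Ste11` and `Sho1--Ste11` are different
variables, a signal's routing information survives passage through a
shared kinase. The translation is deterministic and parameter-free — the
network definition corresponds to a unique Boolean model.

## Update-rule semantics

**Reactions.** A reaction fires when its components are present and its
contingency context holds:

$$r(t+1) = \mathrm{comp}_A \wedge \mathrm{comp}_B \wedge
  \bigwedge_{e \in \text{required}} e \wedge
  \bigwedge_{e \in \text{inhibiting}} \neg e$$

Boolean-node effectors are flattened recursively, so generated rules
contain only elemental atoms; cyclic node definitions are an error naming
the cycle. Signs `0` (no effect) and `?` (unknown) never contribute.

**Contingency policy.** Boolean simulation cannot represent quantitative
modifiers, so the default `"strict-qualitative"` policy reads `K+` as `!`
and `K-` as `x` — the translation used when deriving a qualitative model
from a quantitatively annotated curation. The `"neutral"` policy drops
them instead; the two builds differ by exactly those conjuncts.

**States.** With $P_{irr}$ the irreversible producers, $P_{rev}$ the
reversible producers and $C$ the consumers of state $s$:

$$s(t+1) = \mathrm{comps} \wedge \Big( \bigvee P_{irr} \vee
  \big( m \wedge \neg \bigvee C \big) \Big), \qquad
  m = \begin{cases} \bigvee P_{rev} & P_{rev} \neq \emptyset \\
  s & \text{otherwise} \end{cases}$$

Empty disjunctions vanish. The two canonical special cases fall out
directly: a state with one irreversible producer and one consumer reads
`producer | (s & !consumer)` (it latches until consumed, and concurrent
production wins over consumption), and a state whose only producer is
reversible simply tracks that producer one step delayed (reversible
products decay when their reaction goes off). The general mixed-producer
formula is our choice for the cases no worked example pins down; it was
selected so that (i) each canonical case is the exact specialisation,
(ii) irreversible synthesis overrides consumption, and (iii) reversible
maintenance is gated by consumers. A reaction that both produces and
consumes the same state resolves production-first and is flagged by the
validator.

**Components, inputs, outputs.** Components and inputs are constants
(their rule is their own atom); they are toggled as initial conditions or
clamps, not updated. Two exceptions make component presence dynamic:
synthesis (`TRSC`) and degradation (`DEG`) reactions act on a
component-presence state that shares its variable with the component.
Outputs are treated like states: each output gets a reversible pseudo
production reaction (`<name>_production`) whose rule is the conjunction of
the contingencies targeting the output, so the output tracks its
conditions with the same delay semantics as any other state.

**Component conjuncts in state rules.** Printed update equations
conventionally omit the component atoms from state rules because
components are constant-true; we conjoin them by default (presence is an
absolute requirement) and expose `components_in_states = FALSE` to
reproduce the bare printed form. Under default initial conditions the two
are trajectory-identical.

**Frozen states.** A state referenced only by contingencies, never
produced, keeps its initial value (rule = own atom) and is reported by
`validate_model()` as `unproduced_state`. This makes the model total
without inventing chemistry.

## Input formats

The quick text format is one reaction per line with `;`-separated
contingency clauses (`sign effector`), case-insensitive signs, `#`
comments, and bracketed names for inputs/outputs. Boolean nodes use a
minimal line grammar `"<NAME> = AND(e1, e2, ...)"` — the original quick
dialect's node syntax is not fully specified anywhere we could follow, so
this package defines its own and documents it as a convention. In tabular
input, node definitions are rows whose target is `<NAME>` with the
operator in the sign column, which keeps the two routes equivalent:
`load_tabular()` and `parse_quick()` of the same content produce identical
models, and `write_quick()`/`write_tabular()` round-trip.

A bracketed name is classified by where it appears: effector-only names
are inputs (constant), names appearing as targets are outputs (dynamic).
A name used in both positions — `[Turgor]` in `simplified_hog()` — is a
single output variable whose value also feeds contingencies, which is how
an input-to-output feedback loop closes without duplicating the node.

The reaction-type registry (reversibility, directedness, produce/consume
templates over the slots `A` and `B`) is data, not code: the built-in
table covers binding, kinase/phosphatase chemistry, phosphotransfer,
ubiquitination, nucleotide exchange, synthesis and degradation, and a
plain-text config (`read_registry()`) can override or extend it. Two
defaults are genuine judgement calls: phosphotransfer (`PT`) is treated
as irreversible (override the registry entry to change this), and
degradation consumes the component-presence state rather than deleting
variables.

## Simulation

**Synchronous.** All non-clamped variables update simultaneously.
`run_sync()` hashes full assignments to detect revisits; because the
orbit of a deterministic map enters its cycle before any repeat, the
first revisit yields the *minimal* period (1 = point attractor).
Perturbation events apply at the start of their step, before rule
evaluation; each event restarts the detection window, and the simulation
keeps stepping while future events remain. A clamp holds its variable
against the rules until a later non-clamp event releases it; a non-clamp
event is a one-shot set from which the variable may immediately recover.
Pulse-like stimuli that the system itself degrades are therefore one-shot
sets, sustained environmental conditions are clamps. `max_steps` defaults
to 1000; an exhausted budget returns an unconverged trajectory, not an
error.

**Asynchronous.** `run_async()` uses random-order full passes: per time
step, a fresh uniform permutation of the variables is drawn and each
variable updates in turn, seeing earlier updates in the same pass. This
is the common "random order" asynchronous scheme of Boolean simulation
engines; we chose it over single-variable-per-microstep updating because
one pass then corresponds to one synchronous step, making the ensemble
mean-activity matrix (fraction of runs true, per variable and step)
directly comparable between regimes. Results are bitwise-reproducible per
seed. Note that under sequential passes a two-variable negative-feedback
cycle (`A* = ¬B`, `B* = A`) has *no* stable configuration — exhaustive
enumeration of both update orders shows every state moves — so its
ensemble means stay strictly between 0 and 1, whereas a mutual-inhibition
toggle settles each run into one of its two point attractors.

**State space.** `enumerate_full()` expands all $2^k$ assignments of the
free variables; components and inputs are excluded from the free set by
default (they are constants, toggled as initial conditions), which keeps
the enumerable space honest. The successor map is a functional graph —
out-degree exactly one — so attractors are its terminal cycles and basins
partition $2^k$; both facts are asserted in the tests. Assignments are
hashed as bit-vectors in the model's declaration order, frozen at build
time, and keyed in hex. Beyond the cap (default $2^{20}$) enumeration
refuses and points to `reachable()`, the breadth-first closure from given
starts, which classifies attractors identically on the (successor-closed)
closure.

## Visualisation

`trajectory_heatmap()` drops variables constant over the whole time
course and orders the rest by hierarchical clustering of their 0/1
profiles. The metric and linkage are not dictated by anything in the
problem; we use Hamming distance (Manhattan on 0/1) with average linkage,
both configurable, and the tests only assert the weak property that
co-regulated cascade members end up near each other. `autoplot()` draws
the conventional yellow (active) / blue (inactive) tile map for
trajectories and ensemble mean-activity line plots for asynchronous runs.

## The fixtures: what they emulate, what they do not

`simplified_hog()` reconstructs a two-module osmostress pathway: a
turgor-dependent phosphorelay whose end product inhibits the MAP kinase
cascade, with the cascade output feeding back to restore turgor. The
reconstruction adds a phosphatase component (Ptc1) with unregulated
dephosphorylations of the cascade phosphosites: without consumers,
irreversibly produced states latch and the feedback loop could not
oscillate — the same knowledge-gap repair that `add_reverse_reactions()`
automates for large curations (there, under the synthetic `ukPPase`
component). With turgor clamped high the model reaches a steady state
with the relay on and the cascade off; clamped low, the cascade fires;
free-running, the loop is a relaxation oscillator (synchronous cycle,
period 32 from default conditions).

`toy_crosstalk()` reconstructs two MAP kinase routes sharing Ste20 and
Ste11, with route identity carried by scaffold/membrane recruitment bonds
(`Ste5--Ste11` vs `Sho1--Ste11`). The exact contingency placement (route
gating on the downstream kinase reactions, Ste20's phosphorylation of
Ste11 unregulated) is pinned so that the bipartite model activates only
the cognate output under a single input while the classical collapse of
the *same* network activates both — the package's headline qualitative
contrast, asserted as a test.

These are toys: they capture update-rule semantics, feedback structure
and specificity routing, not the size, redundancy, or noisy curation of
real network reconstructions. Passing tests on them validates the
translation and simulation machinery; it says nothing about the
biological completeness of any particular curation, which is exactly what
iterating `validate_model()`/`run_sync()` on a real network is for.

`random_model()` generates valid seeded models for property tests
(determinism, symbol audits, oracle equivalence); its contingency
effectors are drawn from states its own reactions produce so that only
the documented `irreversible_only` notes appear.

## The classical export

`build_classical()` is deliberately a heuristic. Component-level Boolean
models are conventionally written by hand from the reaction-graph
topology; our automatic construction — sources of reactions with
non-negative net contingency context activate their targets, consuming
chemistry and net-negative contexts inhibit, undirected bindings
activate both partners, `OR(activators) & !OR(inhibitors)` — exists to
produce a faithful representative of that practice for comparison, not a
canonical translation. A component with inhibitors but no activators
keeps its own value while uninhibited. Its role audit (no state or
reaction variables) and the specificity contrast are the only properties
we claim for it.

## Numerical and engineering choices

* Expression trees simplify eagerly (constant folding, single-child
  collapse, same-operator flattening) so generated rules match the
  compact conventional form; structural equality is order-sensitive,
  which lets tests compare against hand-written equations exactly.
* Rules are compiled once to R expressions over a positional logical
  vector; simulators evaluate those, not the trees.
* Bond states are order-normalised lexicographically (`A--B` ≡ `B--A`);
  reaction ids split unambiguously on `_` because component names may not
  contain underscores.
* `.bnet` export sanitises ids (`--` → `_bnd_`, `-` → `_d_`, braces
  dropped, brackets to underscores) and emits the alias table alongside,
  since downstream Boolean tools reject punctuation.
* Degenerate inputs are defined, not errors: the empty model builds an
  empty Boolean model, an empty disjunction is constant false, a state
  with neither producers nor consumers freezes, and duplicated quick
  lines merge.

## Problem sizes

The test suite and the acceptance script run entirely on generated
inputs: fixtures of 10–30 Boolean variables, exhaustive checks over all
$2^k$ states for $k \le 10$, asynchronous ensembles of 60–400 runs over
20–25 passes. These sizes give exact (enumeration-backed) oracles while
keeping the default suite in the tens of seconds; the machinery itself
has no such limits beyond the documented enumeration cap.

## Package shape

Core objects — expression trees, models, trajectories, transition graphs —
are S3 structures, because they are trees and graphs. Every tabular
surface (reaction and contingency lists, diagnostics, rule tables,
long-form trajectories and activities, attractor summaries) is a tibble,
with `tidy()`/`glance()` verbs and `autoplot()` methods, so analyses
compose with the usual data-frame tooling.

## Known limitations

* No stoichiometry, compartments, or domain/residue resolution beyond the
  modification label; no multi-valued or threshold logic; no
  parameterisation of any kind.
* Attractor computation is explicit enumeration, not symbolic (BDD);
  complete state spaces are for small models only, by design.
* The classical export is illustrative (above), not a general-purpose
  component-model generator.
* Tabular input is delimiter-separated text; native spreadsheet input is
  out of scope (export sheets to TSV/CSV first).
* No continuous-time (Gillespie-style) asynchronous semantics and no ODE
  transformation.
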