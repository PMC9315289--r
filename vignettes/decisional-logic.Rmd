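---
title: "Decisional logic networks for adherence trajectories: models, fitting, and intervention search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decisional logic networks for adherence trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adherenet)
```

## The modeling problem

Long-term daily medication — adjuvant endocrine therapy after ER+ breast
cancer is the motivating case — is abandoned early by a large fraction of
patients, and the decision to stop is not a one-shot event: it emerges from
the interplay of side-effect burden, quality of life, worry about
recurrence, trust in the care team, cost pressure, routines, and
demographic context, all shifting over years of treatment. `adherenet`
models this process as a *discrete decisional logic network*: a directed
graph whose nodes are behavioral, treatment and demographic factors, each
holding a qualitative activation level (low / nominal / high by default),
and whose signed edges carry the causal pushes one factor exerts on
another. Time is implicit: the network advances in decisional steps, and a
patient's year-to-year assessments are treated as snapshots of that
process.

## The update rule

Each edge has two decisional kinetic parameters: a perception threshold
$\theta \in \{1, \dots, L_\mathrm{source} - 1\}$ — the minimum level the
source must reach before the target perceives it — and an integer logic
weight $w$ (by default weak = 1 or strong = 2). For a node $v$ in state
$s$, let

$$A(v, s) = \sum_{\substack{e\,:\,u \to v \text{ activating} \\ s_u \ge \theta_e}} w_e,
\qquad
B(v, s) = \sum_{\substack{e\,:\,u \to v \text{ inhibiting} \\ s_u \ge \theta_e}} w_e .$$

The *network image* $I(s)$ suggests the next level of every node at once:
$v$ moves up one level if $A > B$, down one if $B > A$, and holds its level
on a tie or when nothing is perceived. Moves are capped at the scale ends.
Demographic *input* nodes (age, education, household income, tumor stage in
the packaged circuit) are copied unchanged — they condition the logic but
are never updated. The pipeline uses the synchronous scheme (all nodes move
together); an asynchronous single-node mode exists for exploration but is
excluded from every reported analysis.

Two design points deserve emphasis, since the qualitative formalism leaves
them open:

* **Step-limited moves.** A node moves by at most one level per step rather
  than jumping to a target level. This matches the "increase or decrease"
  reading of qualitative activation and guarantees gradual change, which is
  what makes one decisional step per annual assessment a meaningful
  fitting horizon.
* **Ties hold.** When activators and inhibitors balance ($A = B$), and when
  no mediator is perceived, the node keeps its level. The alternative
  (decay toward nominal) builds an attractor at the nominal profile into
  the dynamics by fiat; holding is the neutral choice.

## Attractors and behavioral inertia

A state that reproduces itself under the image — or a cycle of states — is
an attractor: a self-reinforcing behavioral configuration that, once
entered, perpetuates its own adherence status. `enumerate_attractors()`
visits the complete state space (refusing spaces above $3^{10}$ states by
default) and returns every attractor with its exact basin fraction;
`sample_attractors()` estimates the same census from random restarts —
1,000 restarts over a 50-iteration horizon by default — and the frequency
with which an end-state recurs estimates its *behavioral inertia*. Cycle
attractors (period > 1) are detected and flagged even though fixed points
dominate in practice. An attractor is *adherent* when the adherence node
sits at its maximum level in every state of the cycle; anything less is a
discontinuation trap.

The two engines are held to exact agreement in the test suite: on random
small circuits, restarting once from every state of the space must
reproduce the exhaustive census — identities, basins, adherence flags —
bit for bit.

## The packaged circuit

`adherence_network()` loads an 18-node, 43-edge circuit over the factors an
annual-assessment adherence study measures (FACT-G quality of life, BCPT
side effects, recurrence worry and perceived risk, health literacy,
numeracy, cost worry, trust in physician, provider satisfaction, coping
deficit, behavioral routines, comorbidity, plus the four demographic
inputs), with adherence to endocrine treatment as the readout node and the
eight clinically actionable factors flagged targetable. The published
figure of the source study's network is not machine-readable, so the edge
list is a *synthetic reconstruction* written from the causal relations its
text describes; every edge in
`inst/extdata/adherence_circuit_synthetic.tsv` is annotated with its
rationale. The structural counts (18 nodes, 43 edges, 8 targetable
levers) are exact; the specific wiring is this package's own, and all
numerical results shipped with the package are computed on it, not
transcriptions of published values. The study text also refers to 16
fitted network nodes against 18 factors; with four immutable demographic
inputs the packaged circuit has 14 dynamic nodes, and we treat the
fitted-node count as reporting convention rather than a structural
constraint.

## Fitting: per-node constraint satisfaction

Observed data enter as discretized longitudinal trajectories — one row per
participant and annual assessment, one integer level per node, missing
markers allowed, plus an adherence status column. `discretize_scores()`
maps raw psychometric scores through per-instrument cut-points (a score's
level is the number of cut-points at or below it); the study instruments'
actual cut-points are not published, so rank tertiles
(`tertile_cutpoints()`) are the default and every cut-point is
configurable.

The fitting contract is one decisional step per assessment interval
(`K = 1`). Under the synchronous rule this makes the search *decompose
exactly*: node $v$'s next level depends only on its own in-edges'
parameters, so the set of parameter combinations reproducing the observed
transitions factorizes into independent per-node constraint-satisfaction
problems. `fit_node_csp()` enumerates each node's full
$(\theta, w)$ grid (lexicographic order, so candidate identity is
reproducible) and keeps the assignments violating no scored transition;
`fit_network()` composes the per-node sets into whole-network candidate
models, lazily, up to `max_models`. Soundness and completeness of this
decomposition are tested against brute-force filtering of the full domain
on hundreds of random single-node instances.

Supporting decisions:

* **Missing levels** in a start state are imputed at the nominal (middle)
  level for perception tests; assessments where a node is unobserved are
  excluded from scoring. This keeps every constraint well-defined without
  modeling the missingness process.
* **Soft coverage.** Real (noisy) data rarely admit a parameter set
  satisfying *every* transition. The retained per-node assignments are
  those with the fewest violated transitions for their node (the exact CSP
  solutions whenever a node is perfectly satisfiable), and a composed model
  is kept when its *transition coverage* — the fraction of scored
  node-observations predicted at exactly the observed level — reaches
  `coverage_min` (default 0.75; `strict = TRUE` demands 1). Because
  coverage decomposes per node at `K = 1`, the enumerated models are
  precisely the maximum-coverage candidates; models that would pass the
  threshold only through deliberately sub-optimal per-node choices are not
  enumerated. The candidate-space size is reported alongside whatever was
  enumerated, and membership of a specific model (e.g. a simulation ground
  truth) is decided against the per-node sets, so it is exact even when
  enumeration was capped.
* **`K > 1`** breaks the decomposition (a node's two-step prediction sees
  the whole network); a depth-first global search with a mismatch budget is
  provided, exact but exponential, for small circuits only.

Fit quality is reported as the Manhattan *alignment error* — the summed
absolute level difference between predicted and observed states —
decomposed by node and by observation; both decompositions provably sum to
the total, and the per-participant balance lets one check that no single
trajectory is represented more poorly than the rest.

## The synthetic cohort generator

Because the source study's raw trajectories are not deposited, the cohort
generator is a first-class module and defines the study conditions the
package is exercised under: 82 participants, 3–7 annual assessments each
(participants with fewer than three are outside the contract), one
decisional step between assessments, random demographic profiles and
dynamic starts, observation noise as ±1-level flips at rate 0.05, and
missingness at rate 0.1. The noise and missingness rates are not stated by
the study; 5% one-level observation slips and 10% skipped scale scores are
what we would call realistic for annual self-report batteries, and they are
fixed once here. `characteristic_trajectories()` builds the eight
reference courses — four discontinuation subtypes (early, mid-course and
late persistent discontinuation, and transient discontinuation with
recovery), each under all-low and all-high demographic profiles — by
pinning the adherence node to the subtype's status pattern while the
remaining nodes evolve under the model.

What the generator deliberately does *not* emulate: item-level psychometric
responses (only scale-level scores), informative missingness, dropout
correlated with discontinuation, and between-participant parameter
heterogeneity (one decisional logic generates the whole cohort). Passing
recovery tests on these cohorts therefore shows the machinery is sound —
the true logic is always among the candidates on noiseless data, and the
candidate space shrinks monotonically as transitions accumulate — not that
real cohorts identify their logic equally well.

## Minimal intervention sets

A persistent non-adherent attractor is, by construction, refractory:
left alone it reproduces itself. `find_mis()` searches clamp combinations
on the targetable nodes — direction "up" holds a node at its maximum,
"down" at its minimum — in increasing size (default at most two nodes, the
"one or two actionable mediators" regime), holding each clamp for
`hold_steps = 5` synchronous steps, then releasing and letting the network
settle. Success requires the post-release attractor to be adherent: a
*sustained* return, not a transient excursion. Supersets of successful
sets are skipped, which is exactly the minimality filter; the result
provably equals exhaustive subset search on desk-scale circuits. A
sustained-clamp mode (never released) exists behind a flag; release mode
is the default because an intervention one must maintain forever is a
different clinical object.

Strategies are scored by *promptness* (steps from clamp onset until the
adherence node first reaches its maximum) and *robustness* (fraction of
noisy replicates still succeeding under per-step ±1 perturbations at
probability 0.05, 100 replicates — values chosen here, as the source gives
none), and ranked lexicographically: size, then promptness, then label.

`consensus_interventions()` runs the search under every candidate model:
each model's persistent non-adherent states are estimated by restart
sampling, the highest-inertia states (default: top 20 per model) are
subjected to the MIS search, and strategies are pooled into a table of
rescued-state counts per demographic stratum (each input node × level),
with support counts across models and a unanimity flag — the shape in
which such analyses are reported. The inertia cap is a deliberate
analysis choice: with frozen demographic inputs the state space shatters
into many rarely-visited end-states, and targeting states a patient
essentially never reaches is neither informative nor computable.

## Reproducibility and the pipeline

`run_pipeline()` chains the stages — load or generate trajectories, fit,
census, consensus — under a single master seed from which every stage seed
is derived, writes all tables as CSV/TSV plus a manifest with content
digests, and is byte-identical across repeated runs at a fixed
configuration. The numbered scripts under `analysis/` run the same stages
interactively at full scale.

Problem sizes used in the shipped checks (chosen to keep every check
exhaustive or near-exhaustive at desk scale): oracle equivalence of the
two attractor engines on 200 random circuits of 2–8 ternary nodes
(restarting from every state); CSP soundness/completeness on 500 random
single-node instances with up to 4 in-edges over the {1,2}×{1,2} domains;
parameter recovery on three independent 82-participant noiseless cohorts;
MIS-vs-exhaustive equivalence on 100 engineered toys of up to 6 dynamic
nodes and 4 targetable levers. The acceptance report runs the full
pipeline under the study-shaped defaults with the model enumeration capped
at 24 and the per-model target list at 8 states.

## Known limitations

* The packaged wiring is a reconstruction; conclusions about *this*
  circuit are conclusions about the package's fixture, not the source
  study's unpublished figure.
* `K = 1` is both the tractability insight and a modeling commitment;
  multi-step fitting is exact only at toy scale.
* The soft-coverage mode enumerates maximum-coverage models only (see
  above).
* Basin frequencies from restart sampling are binomial estimates; with
  frozen inputs the estimate conditions on the input distribution being
  uniform, which is a choice, not data.
* Cycle attractors are reported but the intervention search starts from
  the cycle's canonical first state; phase-dependent rescue is not
  explored.
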