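---
title: "Methods: a desk-scale knowledge-graph framework for distributed self-driving laboratories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale knowledge-graph framework for distributed self-driving laboratories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package is

`kgsdl` re-creates, at desk scale and without hardware, the architecture of a
distributed self-driving laboratory (SDL) orchestrated through a dynamic
knowledge graph. A scientist's goal request — objective thresholds, a
four-dimensional search space, participating labs, an experiment allowance —
is translated into triples; autonomous software agents then run
design–make–test–analyse (DMTA) cycles as chains of *derivations* (recorded
units of agent work with typed inputs, outputs and logical timestamps) over a
shared triple store. The "make/test" step is a seeded flow-chemistry
simulator rather than a robot, so the complete closed loop — collaborative
multi-lab cost–yield optimisation with full provenance — can be executed and
verified on one CPU.

The chemistry emulated is the base-catalysed aldol condensation of
benzaldehyde (**1**) with acetone (**2**), catalysed by NaOH (**3**), giving
benzylideneacetone (**4**) with dibenzylideneacetone (**5**) and further
condensation products as side products. The design variables are the molar
equivalents of acetone and NaOH (relative to benzaldehyde), the reactor
residence time, and the reaction temperature. The objectives are percent
yield (maximised) and run material cost per mole of benzaldehyde
(minimised).

# The triple store and its time

All shared state lives in an in-memory triple store (`kg_new()`,
`kg_add()`, `kg_query()`) with Turtle export/import. Three choices matter:

* **Logical time.** The store keeps a single monotonically increasing write
  clock; every write advances it, and entities record their last-write tick.
  There is no wall-clock anywhere, which makes every campaign trace exactly
  reproducible. Derivation staleness (`is_outdated()`) is "some input was
  written after I finished".
* **Deterministic IRIs.** Instance IRIs (`kg:ReactionExperiment_<uuid>`) are
  minted from a seeded Lehmer-generator sequence that is independent of R's
  RNG, so provenance exports are byte-stable and minting never perturbs the
  simulation's random stream.
* **Restricted Turtle.** No RDF library is available in the target
  environment, so the writer emits (and the reader accepts) a restricted
  Turtle dialect: prefixed names, typed literals, one triple per line. Round
  trip is set-identical by construction and tested, including unicode
  literals ("°C"). This is a provenance format, not a general RDF engine —
  there is no SPARQL, OWL or blank-node support, which the package also does
  not need.

# The derivation engine

Agent work is coordinated through derivations: `create_derivation()` writes
a Requested derivation with declared inputs and *placeholder outputs* (typed
IRIs that exist from creation but are filled on completion), which is how a
DMTA chain is pre-wired before any stage has run. `poll_and_execute()` runs
one agent's ready derivations (all inputs exist, all upstream producers
Finished), marks InProgress, and writes outputs + Finished + timestamp
atomically; a handler exception becomes a terminal Error without partial
outputs. `run_until_quiescent()` interleaves agents round-robin in
registration order, which is deterministic and starvation-free.

When nothing can run but Requested derivations remain, the engine separates
derivations transitively downstream of an Error (expected under fault
injection; reported as `blocked`) from genuine deadlocks (cyclic or
unsatisfiable dependencies; reported as `deadlock` with the blocked IRIs).
An error in one lab's chain therefore never stalls another lab's chain —
the property that lets a campaign survive losing hardware mid-run.

The conceptually cyclic DMTA loop is realised as a fresh acyclic chain per
iteration: each goal-iteration derivation plans DoE → Schedule → Execution →
Analysis plus a progress-evaluation step, with new IRIs each cycle.

# Goal agents

`parse_goal_request()` instantiates the goal set: one Goal node per
objective (direction + threshold), a Restriction (experiment allowance and
a logical-tick deadline), participating labs and per-variable bounds.
`evaluate_progress()` runs after every analysed experiment and decides:

* **StopGoalsMet** — some Pareto point satisfies *every* goal threshold
  jointly. Joint satisfaction was chosen over per-objective bests because
  thresholds on a Pareto front are only meaningful together; with the
  default fixture thresholds (yield ≥ 90%, cost ≤ 3.0) the cost goal is
  deliberately aspirational, so default campaigns terminate on resources,
  as the real campaign did.
* **StopResourcesExhausted** — allowance 0 or deadline passed. The
  allowance is decremented for every physically executed experiment,
  including abnormal ones: materials are consumed regardless of data
  quality.
* **Continue** — a new goal-iteration derivation is spawned *for that lab
  only*. Labs iterate asynchronously: each starts its next design as soon
  as its own analysis finishes, pulling whatever cross-lab history exists
  at that tick. The just-finished experiment becomes historical data for
  all labs' subsequent designs.

# Design of experiments: TSEMO

The DoE agent gathers all analysed, non-abnormal experiments across all
labs (zero-yield points included — they are information, not noise) and:

* below `n_init = 8` points: draws from a campaign-level Latin hypercube
  over the search space (space-filling initialisation; 8 points is a
  minimal covering for 4 continuous dimensions);
* from 8 points on: Thompson-sampling efficient multi-objective
  optimisation. One Gaussian-process surrogate per objective
  (squared-exponential ARD kernel, inputs scaled to the unit cube,
  responses standardised, hyperparameters by marginal-likelihood
  maximisation with warm starts across iterations and random restarts);
  one approximate posterior *sample path* per objective via spectral
  (random-Fourier-feature) approximation, default 500 features; NSGA-II
  (SBX crossover η=15, polynomial mutation η=20, default population 100 ×
  100 generations) run on the two sampled functions; the candidate with
  the largest hypervolume improvement over the current front (evaluated in
  sampled-objective space at the training inputs) is proposed. All
  settings are config-exposed; the test suite scales the evolutionary
  search down (population 40–60, 20–30 generations, 150–200 features) to
  desk runtime, which measurements showed costs ≈0.5% of recovered
  hypervolume — well inside the acceptance margin.

The cost objective is modelled by a GP like the yield even though cost is
an exact linear function of the equivalents: the optimiser stays
objective-agnostic, as the data-driven loop it emulates treats both as
sampled observations.

Pareto fronts (maximise yield, minimise cost) are computed by a sort-based
sweep and cross-checked against an O(n²) dominance oracle; 2-D hypervolume
is the standard rectangle sweep, cross-checked against a Monte-Carlo
estimate. The campaign's hypervolume trace uses one fixed reference point
(yield −5%, so zero-yield points still dominate it; cost = the dearest
search-space corner + 10%), making the trace monotone non-decreasing — the
stopping diagnostic.

# Scheduler and digital twins

Each lab twin mirrors a flow rig (three pumps + reactor) and an HPLC unit,
with state and stock also written as triples. Translating a condition to
equipment settings solves the linear system: total flow = reactor volume /
residence time, and each co-feed's molar flow ratio to benzaldehyde equals
the requested equivalents given purity-corrected feed concentrations
(0.5 M benzaldehyde with internal standard; 6.73 M acetone; 0.1 M NaOH;
purities 0.99/0.99/0.97). Stock is decremented by per-run dispense volumes
scaled to a fixed benzaldehyde injection volume (2 mL), atomically — a run
is refused before any depletion if stock is short. "Most appropriate
hardware" is implemented as a feasibility filter (rig idle, HPLC ok,
temperature/residence/pump-flow ranges, stock) followed by a deterministic
longest-idle-first tie-break.

The onboarding gate runs two control conditions through each lab's full
execute-and-analyse path. With reference yields supplied (the onboarding
case: conditions previously validated on a trusted rig) each lab is
compared to the reference; without them the comparison is the cross-lab
mean — which with exactly two labs cannot attribute an inconsistency to
one side, an identifiability limit the gate makes explicit by failing both.
Default tolerance is 5% relative; the value the real system used is not
public, and 5% sits above the ≈1.4% yield noise implied by the default 1%
chromatogram area noise.

# The physical simulator

An isothermal plug-flow reactor with constant density and no axial
dispersion, integrated by fixed-step classical RK4 (no ODE-solver package
exists in the target environment; the system is non-stiff at these rates
and RK4 preserves the linear atom-balance invariant to machine precision):

* r1 = k1(T)·[B][Ac][OH⁻] (product formation)
* r2 = k2(T)·[P][B][OH⁻] (dibenzylideneacetone)
* r3 = k3(T)·[P][Ac]²[OH⁻] (lumped further condensation with acetone)

with Arrhenius k(T) = k_ref·exp(−Ea/R·(1/T − 1/T_ref)) and NaOH treated as
a catalyst ([OH⁻] constant along the reactor). The benzaldehyde atom
balance [B] + [P] + 2[D] + [X] = [B]_in holds at every output within 10⁻⁶
relative (tested).

**These kinetics are declared fixtures, not the true chemistry.** No rate
law for this system is published in the source the package emulates. The
parameters (k1_ref = 1.6, k2_ref = 0.5 L² mol⁻² min⁻¹, k3_ref = 0.010
L³ mol⁻³ min⁻¹, Ea = 55/70/50 kJ mol⁻¹, T_ref = 323.15 K) were chosen
*once*, before the acceptance tests existed, so that the simulator
reproduces the qualitative behaviour reported for the real system: yield
increases with temperature over 30–70 °C; yield is unimodal in acetone
equivalents, rising to a peak near 25–30 and falling beyond it (the r3
channel — the explicit form of "further condensation products" — is what
makes the drop decisive; dilution alone proved too weak once the
residence-time effect was kept appropriately minor); and yield correlates
much more weakly with residence time (Spearman ≈ 0.4) than with
temperature (≈ 0.8) over the 2–10 min window. Maximum attainable yield in
the default space is ≈ 92–93%.

The chromatogram synthesiser emits one peak per species above a 10⁻⁴ M
detection limit, area = response factor × concentration × (1 + ε) with ε ~
N(0, 1%), small retention jitter, and an unidentified impurity point when a
feed contains impurities. Two injectable faults reproduce the failure
modes the real campaign reported: `is_peak_shift` displaces the
internal-standard peak outside its window leaving a small spurious peak
inside it (the mis-assignment yields a grossly superphysical computed
yield, triggering the abnormal path and taking the hardware out of the
campaign); `product_peak_shift` moves the product peak just outside its
window (computed yield 0%, retained in history).

# Quantification and indicators

Yield uses single-point internal-standard quantification: n_product =
(A_product/A_IS) × RRF × n_IS with RRF = RF_IS/RF_product, and the internal
standard premixed in the benzaldehyde feed so n_IS/n_B is the feed
concentration ratio. With noise off this is an exact algebraic inverse of
the synthesiser (tested to 10⁻⁶ over 10³ random conditions). Run material
cost counts pump-sourced chemicals only (benzaldehyde + internal standard +
feed solvents, acetone, NaOH) and is exactly linear in each equivalence
variable. E-factor is (total dispensed feed mass − product mass)/product
mass; space–time yield is product mass/(reactor volume × residence time)
after scaling the run to a standard 5 mL benzaldehyde injection. Yields
above 103% (100% plus a 3σ noise band) or a failed internal standard flag
the run abnormal: it stays in the provenance graph but never enters any
surrogate training set.

# What a green test does and does not establish

The synthetic world reproduces the *shape* of the real campaign — trends,
failure modes, asynchronous collaboration, provenance — not its numbers.
Real HPLC drift, pump pulsation, thermal transients, detector physics and
vendor-dependent prices are all absent; prices, response factors, reactor
volume and pump limits are invented fixtures. Consequently the acceptance
suite is property-based (oracle equivalence, conservation, workflow
correctness, determinism, behavioural mirrors of the reported failures)
and deliberately asserts no real-world number: the real campaign's
headline values (93% best yield, 65 points, E-factor 26.17, STY 258.175
g L⁻¹ h⁻¹) came from hardware and chemicals this package does not model
quantitatively.

# Numerical and design choices, in brief

* JSON configuration (no YAML parser in the target environment); schema
  checked by `validate_config()` before any run.
* GP noise floor 10⁻⁸, jitter 10⁻⁸ on kernel diagonals; duplicate inputs
  with conflicting responses are absorbed into the noise term.
* Degenerate (constant) objectives fall back to a prior-only GP with a
  warning; a failed evolutionary search falls back to a random in-bounds
  proposal with a warning.
* NSGA-II clamps to the unit cube, so proposals can lie exactly on a
  bound; random/LHS proposals are strictly interior.
* Control runs are executed before the goal set exists and are not
  recorded as experiment entities; lineage queries on entities without a
  DoE ancestor return empty with a notice.
* Equipment state machine: Idle ↔ Busy (rig), Ok ↔ Faulty (HPLC), any →
  OutOfService (terminal for the campaign, with a logged maintenance
  notification standing in for the real system's email channel).

# Known limitations

Single-process simulated asynchrony (logical ticks), not network
distribution; no SPARQL endpoint or OWL reasoning; box bounds only (no
mixed-integer variables or constraint handling); one proposal per lab per
iteration; terminal Error state with no retries. These mirror the stated
scope of the build.
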