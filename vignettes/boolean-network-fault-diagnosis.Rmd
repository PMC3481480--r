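---
title: "Boolean network modeling and stuck-at fault diagnosis of the oxidative stress response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean network modeling and stuck-at fault diagnosis of the oxidative stress response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolfault)
```

## The model

`boolfault` works with synchronous Boolean networks: a set of binary
gene/protein nodes, each with a predictor function over the nodes, all
updated simultaneously at every time step.  Exogenous signals (here the
single `Stress` input) are *not* part of the state vector — they are
per-step inputs, which is what makes the network a sequential circuit
with primary inputs rather than an autonomous map.  Constant nodes
(here `SMP = 1`, the ubiquitously expressed small Maf proteins) are
likewise excluded from the state vector, so the shipped oxidative stress
model has a 6-bit state `[ROS Keap1 PKC Nrf2 Bach1 ARE]`, first bit most
significant, and 64 states; the state `010010` is written `18`.

Two deliberate semantic choices:

* **Strictly synchronous updating.**  No asynchronous mode is offered.
  All steady-state claims in the package (attractors, transients,
  homing) are claims about the synchronous dynamics.
* **Attractors are defined per fixed input.**  `build_stg()` freezes one
  input assignment and builds the functional graph (out-degree one) on
  all `2^n` states; `find_attractors()` enumerates its cycles.
  Time-varying inputs are handled by `simulate_network()` only.

## Compiling pathway segments

A *pathway segment* `A →t:a,b B` is a promise from the experimental
literature: if `A` holds value `a`, then `B` takes value `b` within `t`
steps.  The compiler (`compile_network()`) only accepts segments with
`t = 1`.  A bound `t > 1` constrains a trajectory, not a single-step
update function, so it under-determines the model; rejecting such
segments loudly seemed safer than guessing a semantics.  All twelve
shipped oxidative stress segments have `t = 1`, so nothing is lost for
the worked system.

For each target the segments write their value into every consistent
cell of a constraint table over at most three predictors (the in-degree
bound keeps tables at Karnaugh-map size).  Three cell states matter:

* **conflict** — some segment writes 0 and another writes 1.  This is
  where biological judgement enters, and we insist it enter as *data*:
  every conflict must be resolved by an explicit override line in the
  compile configuration, never by a heuristic in code.  The shipped
  configuration (`inst/extdata/oxidative_stress_overrides.txt`) is
  *reconstructed* so that compilation reproduces the published update
  rules; the original cell-by-cell maps are not available, so the file
  says so.  The biologically interesting case is the ARE cell
  `Nrf2 = 1, Bach1 = 1, ARE = 0`: both the activator and the repressor
  are up, and the resolution "ARE turns on" encodes Nrf2 relocating into
  the nucleus while Bach1 relocates out.
* **don't-care** — no segment touches the cell.  By default these are
  left free for the minimizer to exploit (standard two-level synthesis
  practice); per-target policies `to_zero`, `to_one` and
  `hold_previous` are available when a modeler prefers a definite
  closed-world completion.
* determined cells are copied through.

The completed table is minimized by Quine–McCluskey prime-implicant
enumeration followed by an exact minimum cover (essential implicants,
then branch-and-bound).  Ties are broken by fewest product terms, then
fewest literals, then lexicographic order of the term strings, so
compilation is deterministic.  Exhaustive exactness is feasible because
tables have at most 6 variables (`minimize_sop()` enforces this); no
Espresso-style heuristic mode is provided, deliberately.

One subtlety worth recording: with free don't-cares the minimizer may
legitimately return an expression that differs from a published formula
*on the don't-care cells only* (for the ARE table it prefers
`!Bach1 | Nrf2 & !ARE`, one literal cheaper than the published
`Nrf2 & !ARE | Nrf2 & !Bach1`).  The shipped configuration therefore
pins the two cells `Nrf2 = 0, Bach1 = 0` to 0 — biologically: no
activator, no antioxidant transcription — which makes the compiled model
*transition-identical* to the published one on all 128 (state, Stress)
pairs, not merely equivalent on specified cells.  The tests verify this
equivalence exhaustively.

Segments interacting with constants are reduced first: a predictor
requirement matching a constant is dropped, a contradicting one makes
the segment vacuous, and segments targeting a constant are ignored.
This is how the "SMP is ubiquitous" modeling rule is realized: the SMP
homodimer segment (`SMP | 1 => ARE=0`) becomes an unconditional
down-regulation of ARE, colliding with the Nrf2 activation segment on
all four `Nrf2 = 1` cells; the overrides resolve all four in Nrf2's
favor except when ARE is already on and Bach1 competes.

## Attractors, basins, transients

`find_attractors()` walks successor pointers with visited marking —
exact and linear in `2^n`, entirely adequate up to the `n = 20` cap on
graph construction (symbolic/BDD methods are out of scope).  Cycles are
stored rotated to start at their smallest decimal so equality is
testable; display can rotate to any anchor (`rotate_cycle()`).

For the fixture the package computes, and the tests pin down: a single
fixed point 18 with basin 64 and maximal transient exactly 4 under
`Stress = 0`; a single 7-cycle
`18 → 50 → 40 → 44 → 45 → 5 → 23 → 18` with basin 64 under `Stress = 1`.
Over that cycle the mean of the ROS bit is 4/7 — the antioxidant loop is
doing its job of keeping the time-averaged ROS below the value 1 it
would have without the feedback — and Nrf2 anti-correlates with Bach1
while correlating positively with ARE (the tests recompute both
correlations from the enumerated cycle states and assert their signs).
Basin sizes and the exact transient depth are
*derived* quantities of this implementation; treat them as predictions
of the model, not published facts.

## The fault model and diagnosis

A fault is a single gene node stuck at 0 or 1 — the node's update
expression is replaced by a constant, so every reader sees the stuck
value from the first update on.  Faults sit on gene nodes, not on
individual fanout branches: the biological reading is a mutated gene,
and per-branch faults have no such reading.  Bridging faults are out of
scope.  `inject_fault()` accepts several nodes at once (multiple faults),
but `build_diagnosis_table()` enumerates single faults only, matching
the single-fault assumption of the diagnosis procedure.

Detection uses the strict criterion: `T` detects `f` iff for **every**
pair of initial states `(q, q_f)` the observable responses differ
somewhere.  We kept the all-pairs quantification verbatim even though a
homing prefix pins the normal machine's state — the homing sequence is
searched and reported separately (`find_homing_sequence()`, BFS over
images of the uncertainty set, hence shortest), but it is not allowed to
weaken the detection test.  Responses are compared *after* each applied
vector; the empty sequence detects nothing.

`generate_test()` searches input sequences of increasing length.  Its
search state is the set of unresolved pairs — pairs whose outputs have
agreed on every step so far — advanced by each input vector and pruned
of newly distinguished pairs.  A sequence detects the fault exactly when
this set empties, so BFS to the empty set returns a shortest detecting
sequence; when the reachable family of pair sets closes without ever
emptying, the fault is *provably* undetectable (the search doubles as a
machine-equivalence check by product construction).  With a 1-bit
primary input and 64 states this is exact, not heuristic; the default
cap of 16 frames keeps single calls bounded, and a capped-out result is
reported as "undetectable within the cap", distinct from "proven".

On the fixture with ARE observable, 11 of 12 faults are detectable with
shortest tests of length 3–9; PKC stuck-at-0 is undetectable (the search
closes at larger caps), an honest consequence of the strict criterion —
for every stress sequence some normal initial state mimics the faulty
machine's ARE trace.  Diagnosis entries carry an output signature (the
positions where a first difference can appear, over all pairs) and
faults with identical sequence+signature share an ambiguity class; a
truncation table records, per generated sequence, the shortest prefix
that still detects each fault it covers.

## The random-network generator

Property tests run against seeded random networks
(`generate_random_network()`): each node draws up to 3 predictors and a
uniform random truth table, optionally with exogenous inputs.  The
3-predictor bound mirrors the modeling rule used for the biological
network; sizes are kept at `n ≤ 12` so exhaustive oracles (brute-force
orbit collection, explicit all-pairs detection, term-count search over
all product terms) stay cheap.  Uniform random truth tables emulate
nothing about real regulatory logic — no canalization, no degree
correlation, no biological bias toward monotone functions — so passing
these suites shows the *algorithms* are correct on arbitrary synchronous
networks, not that the biology is right.  The biology is carried by the
fixture and its exhaustively checked published behavior.

Problem sizes used by the shipped suites: exhaustive checks on all 64
fixture states; random networks of 3–8 nodes across ~20 seeds for basin
properties; 3–6 nodes for the attractor oracle; 3–5 nodes with 50 seeds
for the detection oracle; minimization oracles on all tables up to 4
variables across 60 random tables.

## Numerical and degenerate-input choices

* State encoding: first declared node is the most significant bit;
  encode/decode are exact inverses and are tested exhaustively.
* Minimization tie-breaks: term count, then literal count, then
  lexicographic; constant tables return constant expressions.
* An all-don't-care table minimizes to constant 0 (no on-set, nothing
  to assert).
* `resolve_table()` refuses any remaining conflict; `hold_previous`
  requires the target among its own predictors.
* Homing search treats a singleton initial uncertainty set as already
  homed (empty sequence); identity-like machines whose states never
  merge fail cleanly (`NULL`).
* Caps: transition graphs at 20 state nodes, pair-set test search at 10
  (the pair space is squared), both overridable or refused with a clear
  message rather than silently truncated.

## Known limitations

* Only `t = 1` segments compile; timed multi-step semantics would need a
  different target object than a one-step update function.
* Exact minimization is limited to 6 variables; there is no heuristic
  fallback.
* Attractor analysis is explicit-state; beyond ~20 bits a symbolic
  engine would be required.
* The diagnosis machinery assumes the fault universe of single stuck-at
  gene faults; bridging faults and per-branch faults are not modeled.
* Probabilistic Boolean networks, multi-valued logic and ODE semantics
  are out of scope.
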