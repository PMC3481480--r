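# boolfault

Synchronous Boolean network modeling and stuck-at fault diagnosis for
signaling pathways, with the Nrf2–Keap1–ARE oxidative stress response as
the worked system.

## The problem

Cells answer oxidative stress with a dedicated transcriptional program:
reactive oxygen species (ROS) destabilize the Keap1–Nrf2 complex, the
liberated transcription factor Nrf2 (helped by the kinase PKC and small
Maf proteins, SMP) binds the antioxidant response element (ARE) and turns
on detoxifying genes, while the repressor Bach1 competes for the same
element and shuts the program down once the insult is cleared.  Failures
of this feedback — a gene locked permanently ON or OFF, as by a mutation —
bias the cell toward aberrant behavior.  `boolfault` lets you

* build a synchronous Boolean network `Υ = (V, F)` either directly from
  update rules or by **compiling timed pathway segments**
  (`A →t:a,b B`: "if A holds value a, B takes value b within t steps")
  through constraint tables and exact two-level logic minimization
  (Quine–McCluskey prime implicants with an exact minimum cover — the
  programmatic Karnaugh map);
* enumerate **attractors, basins and transients** of the exhaustive state
  transition graph under a fixed input;
* treat the network as a **sequential circuit** and diagnose single
  stuck-at faults: fault injection, the strict all-initial-state-pairs
  detection criterion, shortest homing (synchronizing) sequences, and
  shortest detecting test sequences found by breadth-first search over
  unresolved state pairs — an exact realization of time-frame expansion at
  this scale.

The shipped six-gene model, state order `[ROS Keap1 PKC Nrf2 Bach1 ARE]`
(most significant bit first), is:

```
ROS'   = Stress & !ARE        Nrf2'  = PKC | !Keap1
Keap1' = !ROS & (Nrf2|Keap1)  Bach1' = !ROS
PKC'   = ROS & !ARE           ARE'   = Nrf2 & (!ARE | !Bach1)
```

with `Stress` an exogenous input and `SMP = 1` a constant.  The same
model is reproduced by compiling the twelve shipped pathway segments with
the shipped conflict resolutions (`inst/extdata/`).

## Worked example

```r
library(boolfault)
net <- fixture_oxidative_stress()

find_attractors(build_stg(net, c(Stress = 0)))
#> 1 attractor(s) over 64 states (Stress=0); max transient 4 step(s)
#>   [1] fixed point, basin 64: 18(010010)

find_attractors(build_stg(net, c(Stress = 1)))
#> 1 attractor(s) over 64 states (Stress=1); max transient 7 step(s)
#>   [1] cycle of length 7, basin 64: 5(000101) -> 23(010111) -> 18(010010)
#>       -> 50(110010) -> 40(101000) -> 44(101100) -> 45(101101)
```

Without stress every trajectory reaches the resting state 18 (`010010`:
only Keap1 and Bach1 on) within four steps and stays; under sustained
stress the network oscillates around a seven-state cycle in which ROS is
repeatedly quenched (its mean over the cycle is 4/7), Nrf2 runs out of
phase with its repressor Bach1 and in phase with the antioxidant output
ARE.

Fault diagnosis with ARE as the observable output:

```r
build_diagnosis_table(net)[, c("fault_node", "stuck_value",
                               "detected", "detecting_sequence")]
#>  fault_node stuck_value detected detecting_sequence
#>         ROS           0     TRUE            0011000
#>         ROS           1     TRUE               0000
#>       Keap1           0     TRUE              00000
#>       Keap1           1     TRUE          000010100
#>         PKC           0    FALSE               <NA>
#>         PKC           1     TRUE              00000
#>        Nrf2           0     TRUE             001000
#>        Nrf2           1     TRUE              00000
#>       Bach1           0     TRUE           00010000
#>       Bach1           1     TRUE            0111100
#>         ARE           0     TRUE              01000
#>         ARE           1     TRUE                000
```

Each bit string is the shortest `Stress` sequence whose observable
response separates the faulty machine from the normal one for *every*
pair of initial states.  Eleven of the twelve single faults are
detectable; PKC stuck-at-0 is not (its effect on ARE is always mimicked
by some normal initial state).  A homing sequence of four quiescent steps
(`0000`) drives the fault-free machine to state 18 regardless of where it
started.

The same functionality is scriptable from a shell via the thin CLI in
`inst/cli/boolfault` (`simulate`, `attractors`, `compile`, `faults`,
`homing`, `dot` subcommands).

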