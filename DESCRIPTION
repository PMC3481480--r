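Package: boolfault
Title: Boolean Network Modeling and Stuck-At Fault Diagnosis for
    Signaling Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synchronous Boolean network models of signaling pathways,
    built either directly from update equations or compiled from timed
    pathway segments via constraint tables and exact two-level logic
    minimization (Quine-McCluskey with Petrick-style minimal cover).
    Provides exhaustive state transition graph construction, attractor
    and basin enumeration, and a sequential-circuit fault diagnosis
    toolkit: single stuck-at fault injection, an all-initial-state-pairs
    detection criterion, homing (synchronizing) sequence search, and
    shortest-test generation by breadth-first search over unresolved
    state pairs, in the spirit of time-frame expansion.  Ships a
    six-gene oxidative stress response network (Nrf2-Keap1-ARE with
    Bach1 repression) as a worked fixture, together with the pathway
    segments and compile configuration that reproduce it.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
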