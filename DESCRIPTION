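Package: chiralstab
Title: Linear Stability Screening for Spontaneous Mirror Symmetry Breaking in
    Reaction Networks
Version: 0.1.0
Authors@R: person("chiralstab", "developers", role = c("aut", "cre"),
    email = "devnull@example.org")
Description: Tools to decide whether a mass-action chemical reaction network
    admits symmetry-breaking unstable steady states, and to emit concrete rate
    constant sets that realize them. Parses plain-text mechanism files with
    enantiomeric species and mirror-image ("dual") reaction pairs, builds exact
    symbolic stoichiometric and kinetic objects, enumerates extreme currents of
    the steady-state flux cone by the double description method, applies
    trace-determinant, principal-minor (mineurs), characteristic-polynomial and
    Frank-inequality instability criteria to Clarke's current matrix, solves the
    resulting linear constraint systems into nested intervals by
    Fourier-Motzkin elimination, samples rate constants, and verifies symmetry
    breaking by numeric integration of the mass-action ODEs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
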