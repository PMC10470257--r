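# chiralstab

Linear stability screening of mass-action chemical reaction networks for
**spontaneous mirror symmetry breaking** (SMSB) — the dynamical route to
biological homochirality.

## Who this is for

Researchers building or testing mechanisms for the origin of
homochirality face a concrete obstacle: a mechanism breaks mirror symmetry
only for particular rate-constant sets, which live in a space spanning ten
orders of magnitude and are hard to find by inspection or simulation.
`chiralstab` reads a mechanism from a plain-text file — an ordered species
list whose first two entries are an enantiomeric pair, a reaction list
with `->` / `<->`, and the *dual pairs* of mirror-image reactions that
must share a rate constant — and answers two questions: *can* a
symmetry-breaking unstable steady state exist, and *which* rate constants
realize one.

## The method

For a network with stoichiometric matrix `S` and kinetic (reactant-order)
matrix `K`, the steady-state fluxes form the cone `{v >= 0 : S v = 0}`
spanned by the **extreme currents** `E` (enumerated here by the double
description method on exact integers).  On the cone, the Jacobian
factorizes (Clarke) as

    J = S · diag(E j) · K · diag(h),

and since `diag(h)` cannot change stability signs, the analysis runs on
the **current matrix** `V(J) = S · diag(E j) · K`, *linear* in the convex
parameters `j`.  Six screening routes are provided: the trace–determinant
plane, stoichiometric network analysis with mineurs /
characteristic-polynomial heuristics, the six-category classification
(synthesis, decompositions, autocatalysis, limited enantioselectivity,
inhibition), the **Frank inequality** `J11 − J12 > 0` on the Jacobian, the
same inequality on `V(J)` (linear, hence sampleable), and the multi-pair
block reduction `V' = A − B` for networks with several enantiomeric
pairs.  Feasible condition sets are solved into nested intervals by
Fourier–Motzkin elimination, sampled, converted to rate constants via
`v = E j`, eigen-checked, and verified by numeric integration of the
enantiomeric excess `ee = (x_L − x_D)/(x_L + x_D)`.

All symbolic computation is exact (sparse multivariate polynomials over
rationals); sampled states are re-checked numerically before release.

## Worked example

The classic two-species autocatalytic network (direct production, decay,
autocatalysis, second-order decomposition, mutual inhibition of L and D)
ships as a fixture:

```r
library(chiralstab)
set.seed(42)
net <- load_fixture("Kondepudi-Nelson")
cat(render_report(list(StoichiometricMatrix = stoich_matrix(net))))
#> StoichiometricMatrix (2x9):
#>   [ 1  0  -1   0  1  0  -1   0  -1 ]
#>   [ 0  1   0  -1  0  1   0  -1  -1 ]

r5 <- run_algorithm(net, 5, list("num-samples" = 3L))  # Frank + SNA
format(r5$frank_inequality)
#> [1] "-j0 - 2*j1 - j4 + j5 > 0"
print(r5$solution)
#> j0 in (0, inf)
#> ...
#> j5 in (max(0, j0 + 2*j1 + j4), inf)
```

The Frank inequality says the flux through the decomposition ray (`j5`)
must beat the combined production/autocatalysis rays — the classical
requirement of autocatalysis plus inhibition.  Each sample is a full rate
set at a racemic steady state:

```r
s <- r5$samples[[1]]
round(s$rate_constants, 4)
#>           k0           k1           k2      ...           k8
#>     101.7814     101.7814   12626.8901      ... 5846394.3943
s$flags
#> unstable: TRUE   frank: TRUE

traj <- integrate_sample(net, s)        # 1e-6 relative perturbation on L
smsb_verdict(traj)
#> [1] "smsb"
```

`unstable`/`frank` mean the Jacobian at the sampled steady state has a
positive eigenvalue whose eigenvector is odd under the L/D swap; the
integration confirms it — the enantiomeric excess grows from `1e-6` to
order one while total concentration stays bounded.  Dual-paired constants
(`k0 = k1`, ..., `k6 = k7`) are exactly equal by construction.

Other bundled fixtures: the explicit reversible Frank model with and
without CSTR flows, a limited-enantioselectivity (LES) model in two
dual-pair variants, a two-pair replicator, a Calvin-type CSTR model with
LES reactions, an asymmetric-autocatalysis scheme (irreversible and
all-reversible), and an APED dimerization block.  `list_fixtures()` lists
them; `parse_model()` reads user files in the same dialect.

Command line:

```sh
Rscript -e 'chiralstab::main_cli()' \
  "--model" "inst/extdata/models/Kondepudi-Nelson.txt" "--seed" "1"
```

## Layout

* `R/` — parsing and validation (`network.R`, `model_io.R`), exact
  symbolic kinetics (`rational.R`, `spoly.R`, `spmat.R`, `kinetics.R`),
  the six analysis routes (`trace_det.R`, `sna.R`, `frank.R`), constraint
  solving and sampling (`sampler.R`), numeric verification (`verify.R`),
  fixtures and CLI (`fixtures.R`, `cli.R`).
* `inst/extdata/models/` — plain-text mechanism fixtures.
* `vignettes/stability-screening.Rmd` — the methods vignette: model,
  assumptions, numerical choices, design decisions, limitations.
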