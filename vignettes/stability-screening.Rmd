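---
title: "Screening reaction networks for spontaneous mirror symmetry breaking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening reaction networks for spontaneous mirror symmetry breaking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralstab)
```

## The problem

Biological homochirality — life's exclusive use of one of two mirror-image
forms of its building blocks — is commonly explained by *spontaneous mirror
symmetry breaking* (SMSB): a racemic steady state of a chemical reaction
network that is dynamically unstable against perturbations that are odd
under the mirror swap, so that an arbitrarily small enantiomeric excess is
amplified.  Whether a given mechanism *can* do this depends not only on its
wiring but on where its rate constants sit in a space spanning many orders
of magnitude.  `chiralstab` mechanizes the search: it reads a mass-action
mechanism from plain text, decides by linear stability analysis whether
symmetry-breaking unstable steady states can exist, and emits concrete rate
constant sets that realize them.

## Model and assumptions

A mechanism is an ordered species list (the first two always an
enantiomeric pair) and an ordered list of irreversible reactions
(reversible lines are expanded forward-then-backward, per line).  Reactions
that map onto each other under the joint swap of all declared enantiomeric
pairs are *dual pairs* and must share a rate constant; multi-way
equalities (e.g. a common CSTR flow constant) are declared as pairs with a
shared first element.  Every rate-equality group must be closed under the
mirror swap — validation rejects groups that tie a reaction to something
other than its mirror image.

Kinetics are mass action only: `v_r = k_r * prod_s x_s^{K[r,s]}` with `K`
the reactant stoichiometry.  All symbolic objects — stoichiometric matrix
`S`, kinetic matrix `K`, velocities, ODEs `xdot = S v`, Jacobian — are
built over exact rationals; no floating point enters a coefficient of a
model-derived object.

## The six analysis routes

1. **Trace–determinant plane** (two species only).  The symbolic trace,
   determinant and discriminant of the Jacobian classify random rate
   points: `det < 0` saddle; `det > 0, trace > 0` unstable; any zero a
   bifurcation.
2. **Stoichiometric network analysis** (Clarke).  On the steady-state flux
   cone `{v >= 0 : S v = 0}` the Jacobian factorizes as
   `J = S diag(E j) K diag(h)`; the concentration factor `diag(h)` never
   changes stability signs and is dropped — a constant of the method, not
   an option.  The *current matrix* `V(J) = S diag(E j) K` is linear in the
   convex parameters `j`, one per extreme ray (column of `E`).  Extreme
   rays are enumerated by the double description method on exact integers.
   Dual-pair flux equalities can be pushed into the cone itself by
   extending `S` with one `+1/-1` row per pair, which shrinks the ray count
   substantially (12 to 6 for the two-species autocatalytic test network);
   `V(J)` is always built from the *original* `S` and `K`.
3. **Six categories.**  Each reaction is matched against six templates
   (synthesis, first-order decomposition, autocatalysis, second-order
   decomposition, limited enantioselectivity, inhibition); the category
   sums give one linear balance equality, and the Frank-type inequalities
   `J11 - J12 > 0`, `J11 + J12 < 0` close the system, which solves
   symbolically into nested rate intervals.
4. **Frank inequality on the Jacobian.**  Reports the steady-state
   equation, the determinant nondegeneracy condition and `J11 - J12 > 0`
   over `(k, x)`; all nonlinear, hence explicitly non-sampleable.
5. **Frank inequality on the current matrix.**  `V11 - V12 > 0` is linear
   in `j` and samples trivially.
6. **Multi-pair reduction.**  With `m` enantiomeric pairs the current
   matrix has exact `[A B; B A]` block symmetry in the (left | right |
   achiral) species order; `V' = A - B` is `m x m` and its spectrum
   governs precisely the mirror-odd modes.  Any of the instability
   heuristics is then applied to `V'`.

Instability heuristics on a current matrix: *mineurs* screens the
characteristic-polynomial coefficients `c_{n-m} = (-1)^m e_m(V)` (sums of
principal minors), emitting `c_{n-m} < 0` only when the expansion contains
a negative monomial — the only way it can go negative for positive `j`;
*characteristic-polynomial* adjoins a fresh symbol `lambda > 0` and demands
`char(lambda) < 0`, which certifies a real positive eigenvalue;
*trace-determinant* applies to 2x2 matrices.  The mineurs route can
produce false positives and negatives; every sample is therefore
eigen-checked numerically and the false-positive count is reported, never
hidden.

## Sampling

Linear equality/strict-inequality systems are solved into nested intervals
by Fourier–Motzkin elimination (the role a CAS plays in the original
method): equalities eliminate pivot variables first (preferring variables
outside the requested order — e.g. the synthesis rate, which the category
balance determines), then variables are eliminated from the last to the
first, leaving each with lower/upper bound expressions in its
predecessors.  Nonlinear systems are linearized heuristically: constraints
in a single variable are reduced to linear bounds through their real roots
(keeping the rightmost feasible component, since all current and rate
parameters are positive); otherwise the symbol occurring in the most
nonlinear monomials (ties: canonical order) is fixed to a pseudo-random
value and the system simplified, repeating up to "simplification-tries"
times.

Numerical choices, all seedable and deliberately documented because the
source method leaves them open:

* random rate draws and substitution values are log-uniform on
  `[1e-3, 1e3]` (kinetic constants span that range in solution phase);
  substitution values are truncated to 4 significant digits so exact
  rationals stay small;
* unbounded-above intervals are sampled as `lb` plus a log-uniform offset
  on `[1e-2, 1e2]`;
* strict bounds are enforced with a relative margin of `1e-9`, and every
  released assignment is re-substituted into the *original* constraints;
* current-space samples convert to rates via `v = E j`, concentrations
  drawn uniformly on `[0.001, 0.01]` with enantiomer partners equal
  (required for the dual-pair rate equality to survive the division by
  concentration monomials), `k_i = v_i / prod x^K`;
* rational coefficients are double-backed; model-derived objects only
  ever hold small integers, while sampling arithmetic past `2^53`
  degrades to 12-significant-digit rationals (samples are re-checked
  numerically, so only display precision is affected).

A sample is *unstable* when the numeric Jacobian at its (by construction)
steady state has an eigenvalue with positive real part, and *frank* when
the Jacobian restricted to the antisymmetric subspace (spanned by
`e_L - e_D` per pair) has one — the operational meaning of a
symmetry-breaking candidate.  When the strict Frank system has no interior
(as in the closed reversible Frank model), sampling falls back to the
closure: boundary states with some currents, hence some rate constants,
exactly zero — flagged as dropped reactions and reported as such.

## Verification

`integrate_sample()` integrates the mass-action ODEs with a hand-rolled
adaptive Dormand–Prince 5(4) stepper (no stiff-solver package is assumed
present); the enantiomeric excess `ee = (x_L - x_D)/(x_L + x_D)` is
tracked per pair.  The initial state is the sampled steady state with a
`1e-6` relative perturbation on species 0 only — small enough that the
early-time `log |ee|` slope matches the dominant antisymmetric eigenvalue
(the suite asserts agreement within 10%).  Verdicts: *smsb* when `|ee|`
exceeds 0.1 (a package convention; the source gives no quantitative
criterion) while total concentration stays bounded; *divergent* when the
total exceeds `1e6` times its initial value — itself diagnostic of
instability without symmetry breaking; *symmetric* otherwise.  With all
dual rates equal and an exactly symmetric start, `ee(t) = 0` identically.

## Design decisions where the source was open

* **Reversible expansion order** is per-line forward-then-backward; the
  two-species autocatalytic fixture is shipped pre-expanded in its
  standard printed order so all reference matrices reproduce exactly.
* **Six-category normalization**: the Frank inequalities are evaluated at
  a symmetric steady state with concentrations scaled to 1, which
  reproduces the concentration-free published forms; the inhibition term
  enters the balance with the sign of the worked instance (the generic
  displayed formula disagrees with its own worked instance, and the
  constraint object carries a note saying so).
* **Replicator fixture**: the published reduced matrix requires the
  replication rates of both replicator pairs to share one forward and one
  backward constant; the shipped fixture declares those groups (the
  model's cross-catalytic symmetry).  Under the shorter dual-pair listing
  the extended cone provably has three extreme rays, not two; both
  readings are covered by tests.
* **Six-category scope**: reactions touching neither enantiomer are
  treated as pure context ("achiral") and excluded from the category
  sums; a chiral reaction matching no template aborts the analysis with a
  structured failure naming it.
* **Extreme-ray order** is canonical lexicographic; the published column
  order is unspecified, so all cross-checks against printed matrices
  compare column *sets* (and printed-order matrices are used where
  entry-for-entry comparison matters).

## What a green test does and does not establish

The fixtures are the mechanisms printed in the source literature; they
exercise two-species autocatalytic networks, open and closed reversible
Frank-type models, limited-enantioselectivity variants, multi-pair
replicator and dimerization blocks, and CSTR flows.  A green suite
establishes that the symbolic pipeline reproduces the published reference
objects exactly, that the ray enumeration agrees with an independent
brute-force oracle on all small fixtures, and that sampled rate sets
verify as unstable/frank by numeric eigenanalysis and integration.  It
does not establish thermodynamic feasibility of sampled constants, global
(nonlinear) stability statements, or behavior of mechanisms outside mass
action.

## Known limitations

Heuristic linearization need not terminate usefully on heavily coupled
nonlinear condition sets (the try budget is reported); the mineurs screen
is a necessary-condition device, not a certificate; symbolic eigenvectors
are exposed only through the 2x2 quadratic; chaotic regimes (observed in
one CSTR fixture with LES reactions) are out of scope, as are bifurcation
continuation and SBML import.
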