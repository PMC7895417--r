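---
title: "Clone consistency: the model algebra, the checker, and the conditioned-medium case study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone consistency: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecon)
```

## The criterion

General ecosystem models treat every population with the same equations;
the biology of a species lives entirely in its parameters. If two
populations carry identical parameters, their individuals are clones as far
as the model can tell, and any split of those individuals between the two
populations describes the same community. *Clone consistency* demands that
the model's output depend only on the clones' summed abundance. It is not a
technicality: an inconsistent model can predict an oscillating community in
one bookkeeping and a quiescent one in another (run
`predator_prey_fixture()` through `simulate_model()` to watch it happen).

`clonecon` encodes the criterion at two levels.

**Impact functions.** A term `phi(x, a)` describing the community's effect
on anything (a growth rate, a niche, a resource) must satisfy four
criteria: populations are interchangeable as (abundance, parameter) pairs
(I1); an absent population's parameters are inert (I2); an all-zero
parameter row makes the abundance inert (I3); and populations with equal
parameters enter only through their summed abundance (I4). The central
structural fact is that every such function is generated from *basic impact
functions* `sum_i zeta(a_i) x_i` with `zeta(0) = 0` (and, for higher-order
interactions, `sum_ij zeta(a_ij) x_i x_j`) by sums, products, scalar
multiples, composition and limits. The package therefore represents model
terms as expression trees over these leaves; `certify_structure()` proves
consistency *by construction* by inspecting the tree, and never claims
anything about opaque leaves.

**Whole models.** A population model must have the form
`dx_j/dt = x_j * phi_j(x, a)` with `phi_j` an impact function: every
dependence on the state happens inside an impact function or through the
single structural factor `x_j`. The factor makes extinction absorbing and
ties the growth of clones to their summed abundance.

## Canonical form and why it matters

Two communities are indistinguishable to *every* impact function exactly
when they share a canonical form: drop populations with zero abundance or
all-zero parameters, lump populations with identical parameters by summing
abundances, sort by parameter value. The abundance-weighted power sums
`sum_i a_i^p x_i` (p = 1, 2, ...) separate canonical forms, which is what
makes the basic impact functions a generating set. `canonicalize()` and
`power_sums()` implement both halves, and the test suite checks the finite
surrogate: for small communities, equal power sums up to order `2n + 1`
imply equal canonical forms.

Lumping uses **exact** parameter equality, deliberately. Clone consistency
is defined for identical parameters; a tolerance here would silently merge
near-ties and manufacture consistency where the model has none. Near-ties
are the numerical checker's business. Likewise "no impact" is pinned at
parameter value zero (the I3 convention); the value is in principle
arbitrary, but we provide no override knob — all built-in constructors and
the sparse samplers use zero, and a second convention would double every
code path for no expressive gain.

## The numerical checker

Structure can certify consistency but cannot refute it; random probing can
refute but never certify. `check_impact_criteria()` implements the
falsification side: for each seeded probe it applies the four criterion
transformations (swap a random index pair; zero an abundance and
re-randomize the parameter row; zero a parameter row and re-randomize the
abundance; force a parameter tie and move a random amount
`z ~ U[-x_1, x_2]` between the tied abundances) and records the worst
relative deviation with a reproducible witness. Design choices:

* **Probe distributions** default to abundances `U[0, 2]` and parameters
  `U[-1, 1]` — order-one communities where every implemented inconsistent
  example deviates by many orders of magnitude more than the tolerance.
* **Ties are constructed, not sampled.** Random real parameters never
  coincide, so I4 always builds its own tie; a `tie_fraction` of base
  probes additionally carries a duplicated row so the other criteria see
  tied communities too.
* **Relative deviation** uses `|u - v| / max(|u|, |v|, 1e-12)`; the floor
  keeps near-zero values from inflating into false positives.
* **Tolerance** defaults to `1e-6` relative. The trajectory-level test
  integrates at `rtol = 1e-10`, four orders tighter, so integration error
  cannot masquerade as inconsistency.
* Evaluation failures (domain errors, non-finite values) mark a probe
  *skipped*, never failed — a term is only condemned on a finite witness.

`check_model_consistency()` lifts this to whole models: each population is
split into clones carrying fractions `theta` and `1 - theta` of its
abundance (parameter rows duplicated; pairwise matrices get row and column
duplicated, which sets all four clone-block entries to the original
diagonal entry), and the split system is compared with the original twice —
instantaneous right-hand sides at `t = 0`, and trajectories on a fixed
101-point grid over the horizon, so verdicts do not depend on
solver-internal steps. Split systems of grossly inconsistent models can be
violently stiff; trajectory integrations are therefore capped (5000 steps)
and, when they bail out, the right-hand-side comparison — which already
witnesses the inconsistency — carries the verdict.

## Dynamics: numerical choices

No ODE-solver package is assumed: the integrator is an in-package adaptive
Dormand–Prince 5(4) with mixed absolute/relative error control
(`atol = 1e-12`, `rtol = 1e-10` by default), PI step-size control, FSAL
reuse, steps clipped to land exactly on output times, a step-size-underflow
error that carries the last valid state, and a divergence guard (`|y| >
1e8`). The case-study models contain the non-smooth clamp
`max(0, z)`; we integrate across its kinks with the adaptive explicit
method (optionally with `max_step`) rather than event detection — at these
tolerances the step controller resolves the kink locally, and the
consistency verdicts sit far above the residual error. The logarithmic
model is defined only for strictly positive abundances; `log(0)` is a
domain error, not `-Inf`, and probes for it are drawn strictly positive.

Frozen populations (used to represent conditioned medium, below) have their
derivative zeroed rather than being removed from the system, so indexing
stays stable and their impact terms keep acting on everyone else.

For the oscillation/convergence dichotomy the package uses an explicit
classifier, since "oscillating" is otherwise in the eye of the beholder:
*converged* means the final distance to the refined fixed point is below
`1e-3` and the distance envelope over the last 20% of the horizon is
non-increasing; *oscillating* means at least three local maxima of the
first series with prominence above 0.05. The unsplit predator–prey fixture
satisfies the latter (its log-abundance dynamics are linear with purely
imaginary eigenvalues — a center), the split system the former (its clone
symmetry adds a damped direction); the acceptance suite asserts only
non-convergence plus oscillation, not the attractor type.

## The model zoo's free choices

* **gLV.** Implemented as `g_j x_j (c_j + sum_i a_ji x_i)` with diagonal
  `a_jj = -1`: self-competition sits in the interaction matrix with the
  same sign convention as the fixed-point system `0 = 1 + b x` used
  throughout the case study; `n = 1` is the Verhulst model with equilibrium
  `c`.
* **Pollination–grazing.** Only the plant's per-capita rate is dictated by
  the science (`g_max` times a Holling type-II saturation of summed
  pollination, minus summed grazing). Insects get constant per-capita
  baseline rates — constants are impact functions, so the whole model stays
  certifiable — and an `is_plant` indicator participates in the clone-split
  rule so plant clones keep plant dynamics.
* **Sparse ensembles.** `sample_general_model()` draws
  `dx_j/dt = x_j g_j prod_k eta_k(sum_i a_jik x_i)` with `eta_k(0) = 1` so
  absent interactions are neutral under the product (the normalization is a
  convention; any other constant could be absorbed into `g_j`).
  Coefficients are nonzero with probability `sparsity`; off-diagonals are
  drawn from `U[-0.5, 0]` (competitive) and the first mechanism's diagonal
  is -1 when drawn. Non-positive couplings keep probe trajectories bounded,
  so the consistency check exercises real dynamics instead of blowups; with
  `sparsity = 0` the model degenerates to pure exponential growth, and with
  one linear mechanism (`eta = 1 + z`) it is algebraically a gLV with unit
  capacities.

## The conditioned-medium case study

The data: each strain `j` grows alone (growth rate `g_j`, capacity `c_j`,
abundances normalized so `c_j = 1`), and in medium containing a fraction
`v = 0.4` of strain `k`'s spent supernatant (conditioned observables
`g_jk`, `c_jk`). The modeling assumption that makes this tractable is
*footprint identification*: a population's abundance doubles as the record
of nutrients consumed and byproducts released. Conditioned medium is then
an ecosystem in which strain `k`'s footprint is present without its cells —
in the package, a population *frozen* at abundance `v * c_k`. The
self-conditioning convention `c_jj = 1 - v` follows: a strain in its own
conditioned medium can only fill the unconditioned fraction of its niche.

**The existing model** modifies Verhulst growth with interaction sums over
`i != j` in both the rate and the capacity. We place the modified capacity
in the denominator of the logistic crowding ratio,

    dx_j/dt = x_j g_j max(0, 1 + sum_{i!=j} a_ji x_i)
                  * (1 - x_j / max(0, 1 + sum_{i!=j} b_ji x_i)),

so that interior fixed points satisfy the linear system
`x_j = 1 + sum_{i!=j} b_ji x_i` (equivalently `0 = 1 + b x`, `b_jj = -1`)
and a capacity *promotion* (`c_ji > 1`) raises the equilibrium, as it must.
The incomplete sums and the bare `x_j` inside the crowding ratio are not
impact functions: the model is clone-inconsistent (the checker witnesses
it), but its fixed points solve a clone-consistent linear system — which is
why equilibrium-based conclusions survive while transients do not.

**The new model** starts from the ansatz of one basic impact function per
measured observable, multiplied so that the capacity factor can
single-handedly stop growth:

    dx_j/dt = x_j * rho_j(sum_i r_ji x_i) * sigma_j(sum_i s_ji x_i).

The experimental constraints pin `sigma(0) = 1`, `sigma(1) = 0`,
`s_jk = (1 - c_jk)/v`, `rho(0) = g_j`; the simplest compliant choices are
`rho(z) = g_j + z` and `sigma(z) = 1 - max(0, z)^q`. The growth
coefficients follow as `r_jk = (g_jk / sigma(1 - c_jk) - g_j)/v` (the
`full` variant), which is singular as `c_jk -> 0` — where the experiment
itself could not have measured `g_jk`. The shipped default (`approx`)
replaces `sigma(1 - c_jk)` by its sharp-saturation limit 1, giving the
well-behaved `r_jk = (g_jk - g_j)/v` at the price of an exactly known
residual in the conditioned-growth constraint:
`-g_jk (1 - c_jk)^q`, about `1e-4` at typical values with the default
`q = 10`. That default trades constraint fidelity (large `q`) against a
continuously differentiable right-hand side (small `q`); both clamped
factors are non-negative, so populations never decline — consistent with a
footprint that cannot be unconsumed — unless dilution is added.
`validate_constraints()` evaluates all four constraint residuals exactly
(the growth-rate constraints are read off as `phi_j`, not finite
differences, because of the structural `x_j` factor), using a
clone-augmented system for the self-conditioning diagonal.

## The synthetic experiment: what it does and does not establish

`synthetic_truth()` draws a ground-truth community in the new model's form:
`g ~ U[0.5, 1.5]`, niche coefficients `s` with unit diagonal and
off-diagonals `U[-0.5, 1.2]`, growth coefficients `r` with zero diagonal
(self-limitation lives entirely in `s_jj = 1`; a growth self-interaction is
not identifiable separately from this protocol's diagonal observables) and
off-diagonals `U[-0.5, 0.5]`; off-diagonals are independently nonzero with
probability `sparsity` (default 0.5). These ranges keep every monoculture
viable and every conditioned culture growing (`g_j + r_jk v >= 0.3`), i.e.
they are the regime in which the laboratory protocol itself is
well-defined.

`simulate_experiment()` emulates the protocol: `g_j` is read off exactly as
`phi_j` at `x = 0`; `c_j` is the monoculture plateau (integrated in chunks
until the per-capita rate drops below `1e-10`, horizon 1000 time units —
the laboratory's 48 h is wall-clock, not model time); `g_jk` and `c_jk`
come from cultures with the conditioning strain frozen at `v * c_k`, the
diagonal from a clone-augmented system and the `c_jj = 1 - v` convention.
`recover_parameters()` closes the loop: `s` is recovered exactly to plateau
tolerance, and `r` up to the closed-form saturation residual
`g_jk (1-c_jk)^q / (v (1 - (1-c_jk)^q))` — zero under the `full` variant.

What the generator does **not** emulate: optical-density measurement noise,
lag phases, regression-based growth-rate estimation (we read the rate off
the model structure), cell death, and dilution schedules (bladder voiding);
a green recovery test therefore establishes the *identifiability and
self-consistency of the derivation pipeline*, not robustness to assay
noise. Fitting the models to real measurements is out of scope.

## Known limitations

* The integrator is explicit; genuinely stiff models (as the existing
  model becomes under strong inhibition) are handled by failing fast and
  falling back to instantaneous comparisons, not by a stiff solver.
* The checker falsifies; it cannot certify a black box, and it probes
  exact clones only. "Nearly identical" populations plausibly cause nearly
  the same pathologies, but no metric for that is implemented.
* No stability/bifurcation analysis, delays, or stochastic dynamics.
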