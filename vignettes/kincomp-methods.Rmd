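---
title: "Kin selection, competitive effort and inequality in fluctuating environments: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin selection, competitive effort and inequality in fluctuating environments: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kincomp)
```

## The model

`kincomp` analyses the evolution of *competitive effort* — a selfish trait
that raises an individual's share of local resources while depleting the
patch's public good — in a haploid, asexual, infinite-island population
with two layers of class structure:

* **individual quality**: each patch holds `n` breeders (default two), half
  high-quality (H) and half low-quality (L), with baseline fecundities
  `q_H >= q_L`;
* **patch state**: patches are resource-rich (R, resource level `mu_R`) or
  resource-poor (P, `mu_P < mu_R`) and switch state between generations
  under a two-state Markov chain.

The chain is parameterised by the stationary rich-patch frequency `p` and
the lag-1 temporal autocorrelation `tau`, the unique two-parameter chain
with those properties: `p_RR = p + (1 - p) tau`, `p_PP = (1 - p) + p tau`.
`tau = 1` freezes patch states, `tau = 0` makes them independent across
generations, negative `tau` makes them alternate; negative values are
feasible down to `-min(p, 1-p)/max(p, 1-p)`, where a transition probability
hits zero.

The life cycle each generation: (1) social interactions and reproduction;
(2) offspring disperse with probability `d` and survive dispersal with
probability `1 - c`; (3) offspring compete for the `n` breeding slots of
each patch, in a fecundity-weighted lottery between the philopatric pool
`O_sigma = (1 - d) T_sigma` and the uniformly redistributed immigrant pool
`I = d (1 - c) E[T]`; (4) winners are assigned quality roles at random
(offspring are identical in quality); (5) patch states transition. All
analytical quantities are derived from exactly this order of events; in
particular, competition happens on the *current* patch type and the state
transition follows settlement.

Fecundity of a quality-`rho` breeder in a type-`sigma` patch expressing
effort `x` when the patch's mean effort is `xbar`:

    f = mu_sigma * ( q_rho_sigma + (x / xbar) * (1 - xbar) )

The multiplicative social term is a personal component (the focal's share
of total effort) times a group component (the remaining public good
`1 - xbar` per unit mean effort). Efforts live in `[1e-6, 1]`; `x = 1` for
everybody is the fully selfish corner at which the social term vanishes.
A useful consequence: total patch output depends on efforts only through
the mean, `F_sigma = mu_sigma (q_H + q_L + (n)(1 - xbar)/1)` per breeder
pair, so group productivity falls linearly in mean effort. Own-fecundity is
*not* globally increasing in own effort: the marginal share gain beats the
actor's share of the depleted public good only while
`n xbar (1 - xbar) > x_own`.

## Relatedness

Pairwise relatedness between patch-mates, conditioned on the current patch
state, satisfies a two-equation linear recursion. Conditioning on the
previous state `gamma` (backward probabilities by Bayes at stationarity),
two random slot winners are both philopatric with probability
`phi_gamma = h_gamma^2` (independent lottery draws — a consequence of
effectively infinite fecundity), are sibs with probability given by the
squared maternity shares, and otherwise inherit the previous generation's
relatedness. The package solves the linear system directly
(`solve_relatedness()`), never by geometric-series truncation, so the
frozen (`tau = 1`) and alternating (`tau = -1`) environments need no
special-casing. Mutation does not enter the recursion; relatedness is pure
identity by descent under neutral clonal inheritance at the resident
demography. In the symmetric limit (`mu_R = mu_P`, `q_H = q_L`) the system
collapses to the classic island-model closed form `r = phi / (2 - phi)`
with `phi = ((1 - d)/(1 - c d))^2`, which the tests use as an exact oracle.

## Reproductive value and selection

The 4x4 class fitness matrix `w` (classes HR, LR, HP, LP) counts the
expected offspring of each class that secure a breeding slot in each class.
Its leading eigenvalue is 1 at any resident demography (patch number and
size are fixed); the right eigenvector gives breeder reproductive values
`v`, the left eigenvector the stable class frequencies `u` (normalised
`sum(u) = 1`, `sum(u v) = 1`; the scale of `v` is arbitrary and the choice
is verified immaterial by test). Dense eigen-decomposition is used —
power iteration would be fragile on the nearly reducible matrices that
arise at `tau` near 1.

Selection on each class-conditional effort is the slope of
reproductive-value-weighted mean fitness on the class's breeding value,
computed the neighbour-modulated way (`selection_gradient()`): a focal
deviant's effect on its own class fitness plus relatedness-weighted effects
on each patch-mate's class fitness, holding the global background (the
immigrant pool, `u`, `v`) at resident values. The partial derivatives are
central finite differences with step `1e-6` — small enough that the
quadratic truncation error (~1e-12 relative) is far below every tolerance
used, large enough to stay clear of cancellation noise.

`hamilton_decomposition()` re-expresses the same gradient as Hamilton's
rule: a primary fecundity cost `-C V`, a relatedness-weighted primary
benefit `B r V`, and a kin-competition cost in which the `B - C` extra
locally produced offspring each displace a uniformly random winner among
the `n` local slots (displacement factor `w_phi / n`), destroying
philopatric reproductive value of the actor and, relatedness-depreciated,
of its mates. Two conventions make this decomposition *exact* rather than
heuristic, and both were adopted after requiring algebraic identity with
the direct gradient:

* the actor's cost `C` is the **total** derivative of its own fecundity
  (personal-share channel plus the actor's own share of the depleted
  public good), not the personal channel alone — `marginal_terms()` still
  reports the two channels separately;
* the displacement factor carries the explicit `1/n`.

With these, `lhs = S / u` class by class (proportionality constant
`kappa = 1/u`), and the suite enforces agreement to `1e-6` relative over
randomised parameter sets. The potential for helping follows by setting the
left-hand side to zero: `A = (r V - K)/(V - K)` with `K` the
kin-competition weight; helping can evolve where `A > 0`, harming where
`A < 0`.

## The ESS solver

`ess_solve()` finds the joint singular point of the four (or eight)
conditional efforts by a damped fixed-point ascent
`z <- clip(z + eta S(z))` with overshoot-halved, capped step (`eta <= 0.5`),
recomputing the full resident state — fecundities, pools, fitness matrix,
eigen-system, relatedness — at every iterate, followed by a Newton polish
on the interior components once the gradient norm is below `1e-4`. The
ascent is globally robust; the polish removes the linear-convergence tail
that otherwise appears when the Jacobian eigenvalues are small (near-frozen
environments). Convergence is declared at gradient max-norm `1e-8`; traits
pinned at a bound with an outward gradient are reported as boundary
classes, not failures. Convergence stability is assessed from the numerical
Jacobian of the gradient map with respect to *resident* trait values
(central differences, step `1e-5`): stable iff every eigenvalue has
negative real part — the standard multidimensional criterion for gradual
trait dynamics. A sign-reversed gradient map is used as a negative control
in the tests. Default initial condition is the interior point 0.5 for every
class; warm- and cold-started solves are verified to agree.

## Inequality and productivity

Within-group inequality is `G_omega = 1 - f_L/f_H`, between-group
inequality `G_beta = 1 - F_P/F_R`; their fully selfish baselines follow by
setting all efforts to 1 (`G0_omega = 1 - q_L/q_H`,
`G0_beta = 1 - mu_P (q_HP + q_LP) / (mu_R (q_HR + q_LR))`). Productivities
are reported relative to the frozen-environment reference
`F(tau)/F(tau = 1)`, computed by an explicit reference solve inside
`tau_sweep()`.

One genuine and initially surprising model feature deserves note. At the
standard parameter set, rich-patch productivity `F_R(tau)` is *not*
maximal at `tau = 1`: it peaks near `tau ~ 0.9` and falls at exact
stability, because the philopatric value component — and with it kin
competition — spikes in permanently rich patches, driving competitive
effort back up. The individual-based simulator confirms the analytic
equilibrium at `tau = 1` (populations started elsewhere climb to it), so
the package reports the reference-relative productivities exactly as
defined and the acceptance suite documents where the sign claims derived
from the near-stable regime break at the frozen corner. The same boundary
layer produces the interior peak of the potential for helping in rich
patches.

## Extensions

**Early-life quality acquisition** (`ess_solve(model = "early-quality")`):
quality is drawn at birth (high with probability `Q`, default 1/2) instead
of being assigned within each patch, so patches come in compositions HH,
HL, LL with binomial frequencies and traits condition on own quality,
partner quality and patch state — eight classes. The fitness matrix is
8x8 with independent quality draws per winner; pair relatedness per patch
state is composition-independent (quality is assigned independently of
parentage), an assumption the simulator can probe. Class frequencies
factorise as patch-state x own-quality x partner-quality, which the tests
assert against the binomial composition law.

**Patch size** (`n > 2`, even, half of each quality): the same code path as
the main model throughout — pools, settlement and the fitness matrix are
written in patch totals, the relatedness recursion generalises the sibship
term to the same-mother probability `sum_rho (n/2) (f_rho/T)^2`, and the
selection gradient picks up `(n/2 - 1)` same-quality and `n/2`
cross-quality patch-mate terms, each weighted by pair relatedness. At
`n = 2` the generalised sibship term reduces exactly to the two-breeder
maternity-share form, which is asserted as the reduction test.

## The individual-based simulator

`simulate_population()` is a finite-population implementation of the exact
life cycle: every individual carries heritable efforts for all four classes
(expressed conditionally) plus neutral infinite-alleles markers; slots are
filled by fecundity-weighted lottery draws; traits mutate at rate 0.01 per
trait per birth with a reflected Gaussian kernel of sd 0.02; marker
mutation is 1e-3 per locus. Defaults: 2000 patches, 20000 generations,
burn-in half the run. Relatedness is estimated from within-patch pairwise
marker identity relative to population-wide identity, with patch-bootstrap
standard errors (`estimate_relatedness()`). Trait-mean Monte-Carlo
uncertainty is estimated from the post-burn-in record with the AR-fitted
spectral density at frequency zero: under weak selection the class means
wander with autocorrelation times comparable to the run length, and naive
or short-batch estimators understate the uncertainty by an order of
magnitude there.

What the simulator does and does not show. It shares the analytical
model's structural assumptions (asexual haploids, non-overlapping
generations, the lottery), so agreement validates the *derivations* —
relatedness recursions, reproductive values, the gradient — not the
biological realism of those assumptions. It adds what the analysis ignores:
genetic drift, mutational variance and stochastic patch dynamics. Two
finite-population effects are therefore expected and observed: marker-based
relatedness estimates carry genealogical noise beyond the patch-bootstrap
SE, and stationary trait means sit a small distance (order of the standing
trait variance, ~0.01-0.04 here) from the infinite-population singular
point, most visibly for the weakly selected classes (poor patches carry a
tenth of the rich-patch resource scale, and the low-quality rich class has
the shallowest fitness landscape). The validation suite compares at face
value — three Monte-Carlo standard errors over replicate runs — and the
residual displacement of the most weakly selected trait means is
documented rather than hidden: the low-quality poor-patch class (whose
selection gradient carries the factor `mu_P = 0.1`) sits consistently
~0.01-0.03 above its singular value across seeds and population sizes, a
stationary mutation-variance effect, while replicate-averaged means of the
other classes agree with the analytics to ~0.01.

## Problem sizes and numerical choices

The shipped tests use a 13-point `tau` grid for the main-model reaction
norms, a 7-point grid for the eight-trait extension, 50 random dispersal
regimes for the closed-form relatedness check, 20 random parameter sets
for the gradient/decomposition identity, and simulator runs of 1000
patches x 10^4 generations (three `tau` values) for stochastic
validation — sizes at which every analytic check is at numerical precision
and the Monte-Carlo bands are a few times 1e-3 wide. Degenerate inputs are
rejected with named-parameter errors (dispersal mortality wiping out all
recruitment, zero mean effort, infeasible `tau` below the transition
feasibility bound); ties in the effort-ordering assertions are resolved by
strict comparisons at tolerance zero, and every linear solve is a direct
dense solve.
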