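---
title: "Modelling evacuation demand curves as a social contagion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling evacuation demand curves as a social contagion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evacsi)
```

## The model and its assumptions

`evacsi` treats the decision to evacuate a disaster risk area as an
irreversible, socially contagious state change: a resident is either
*undecided* (susceptible, `S`) or *decided to evacuate* (infective, `I`),
and once decided never reverts. The population of each of the `N`
communities is split into three individual types — Impressionable, Neutral
and Standpat — that differ only in how strongly they respond to the same
total influence, via the effective transformation rates
`gamma_1 > gamma_2 > gamma_3 > 0`. All other parameters are shared across
types.

For group `(j, k)` (community `j`, type `k`) with population
`Q_jk = S_jk + I_jk`, the decision rate is

$$\frac{dI_{jk}}{dt} = \gamma_k\Big[\lambda_0\frac{S_{jk}}{Q_j}I_j
  + \frac{S_{jk}}{Q_j}\sum_k\sum_{i\neq j} I_{ik}\,\lambda(d_{ij})\,h(d_{i0})
  + S_{jk}\,f(d_{j0},t) + S_{jk}\,w(t)\Big]$$

The four terms are:

1. **Within-community contagion.** Every decided resident contacts
   `lambda0` people per hour inside the community; contacts with undecided
   residents convert them at rate `gamma_k`.
2. **Between-community contagion.** Contact frequency across communities
   decays with their separation through a Gaussian kernel
   `lambda(d) = lambda0 * alpha / (sqrt(2*pi)*sigma) * exp(-d^2/(2*sigma^2))`,
   and each contact is weighted by `h(d_i0) = a1*d_i0 + b1`, the distance of
   the *source* community to the risk source: an evacuation message from a
   low-risk (distant) community is more surprising, hence more persuasive.
   This is the mechanism behind shadow evacuation.
3. **Geographic decay** `f(d, t)`: the direct, location-driven pressure to
   leave, largest near the source and fading with time (the hazard itself is
   assumed static).
4. **Warning degree** `w(t)`: a piecewise forcing shared by the whole risk
   area; each official order injects an effect that decays until the next,
   stronger order arrives.

Assumptions worth keeping in mind: the model is a *continuum* (counts are
real numbers; "people" values are rounded only for display), group-level
(no individual-level network), and every influence is non-negative, so
`I_jk(t)` is monotone non-decreasing and eventually everyone evacuates —
for mild emergencies the realistic content is the early part of the curve.

## Parameters, units and defaults

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `gamma` (3) | per-type effective transformation rates | — | 0.5, 0.3, 0.2 |
| `lambda0` | within-community contact frequency | h⁻¹ | 0.25 (one contact per 4 h) |
| `alpha` | between- vs within-community contact scaling | — | 0.01 |
| `sigma` | contact-kernel width | km | 1 |
| `a1`, `b1` | slope / intercept of `h(d)` | km⁻¹, — | 1, 0.1 |
| `a2`, `b2` | numerator / time coefficient of `f(d,t)` | —, h⁻¹ | 0.01, 0.01 |
| warning pieces | `(t_issue, a, b)` per order | h, —, h⁻¹ | (0, 0.01, 0.001), (60, 0.2, 0.01) |

The defaults are the reference values of the case study shipped as
`reference_parameters("table1")`; a second preset,
`reference_parameters("table3")`, carries the sensitivity-analysis
reference set (it differs in `alpha`, `a1`, `a2`, `b2` and the first
warning piece). Distances are in km and times in hours throughout.

## Algebraic choices in the influence functions

Two of the printed functional forms in the source material admit more than
one reading, so both are implemented and the choice is explicit:

* **Geographic decay.** The default is the *combined* form
  `f(d, t) = a2 / (d^2 + b2*t + 10)`, which is monotone non-increasing in
  both arguments, finite at `d = 0`, and matches the printed `+10` offset.
  A *separable* alternative `a2/d^2 * 1/(b2*t + 10)` is available via
  `location_params(f_form = "separable")`; it diverges at `d = 0` and is
  therefore not the default.
* **Warning forcing.** The default mode `hyperbolic_reset` evaluates
  `a_i/((t - t_i) + 10) + b_i` on piece `i`, restarting the decay clock at
  each issuance — every new order injects a fresh effect that then weakens
  "before the next degree of warning comes". `hyperbolic_global`
  (`a_i/(t + 10) + b_i`, one global clock) and `linear` (`a_i*t + b_i`,
  with `validate_linear_schedule()` checking the conventional slope and
  issuance-value orderings) are kept as modes.

Construction of a `warning_schedule()` enforces the **jump-up property**:
at every issuance the new piece's starting value must exceed the previous
piece's left limit, because a higher warning degree means a stronger
effect. One consequence: a scan of the first piece's `a` coefficient over
its full published range would, near its upper end, make the first piece
decay to a value *above* the second piece's start and is rejected — scan
ranges must respect the schedule's internal ordering.

`h(d)` grows without bound in `d` as specified; no cap is applied by
default, but `location_params(h_cap = )` provides a configurable ceiling
for layouts with outlying communities.

## Initial conditions

Initial data are almost never available for every group, so
`initial_state()` spreads a single observed anchor — `count` evacuated
people of type `k*` in community `j*` at `t = 0` — over all groups:

$$I_{jk}(0) = \frac{\gamma_k}{\gamma_{k^*}}
  \Big(\frac{d_{j^*0}}{d_{j0}}\Big)^{p}
  \frac{Q_{jk}}{Q_{j^*k^*}}\, count$$

i.e. initial evacuated *fractions* scale with the type's responsiveness and
fall off with the `p`-th power of distance to the source (`p = 3` by
default; 1 or 2 for a weaker distance effect). Note the ratio is written
with the anchor distance in the numerator: fractions are *inversely*
proportional to distance, which is the stated intent of the rule even
though one printed form of it has the ratio upside down. The anchor
identity (`I = count` at the anchor itself), the `gamma`-ratio scaling and
the inverse-power scaling are all exact and tested. `t = 0` is defined as
the issuance of the first evacuation order; anything that happened earlier
enters only through the anchor.

## Numerical scheme

The `3N` equations are integrated by fixed-step **forward Euler**
(`simulate_evacuation()`), the scheme the model was designed around: the
case study uses `dt = 1` h over a 120 h horizon, where one step per hour
matches the hourly reporting of demand. Three guards make the scheme safe:

* the state is clamped to `[0, Q_jk]` after every step (with the default
  parameters and `dt = 1` h clamping never triggers — asserted in tests —
  but it protects exploratory parameter choices at large `dt`);
* every warning issuance time must lie on the grid, so the upward jump of
  `w(t)` is resolved exactly at the issuance (off-grid breakpoints raise an
  error asking for a compatible `dt`); `w` is evaluated right-continuously,
  so the step leaving `t = 60` already uses the stronger order;
* rates are non-negative by construction, so trajectories are monotone and
  conservation `S_jk = Q_jk - I_jk` holds identically (only `I` is stored).

Accuracy is validated against the closed-form logistic solution of the
reduced model (one community, one type, between-community, geographic and
warning terms off), where the exact solution is
`closed_form_logistic(t, Q, I0, rate = gamma * lambda0)`. At `dt = 0.01` h
the maximum relative error over 120 h is below 1%, and halving `dt` halves
the error (first-order convergence), as the test suite and the acceptance
script verify. The between-community weight matrix
`lambda(d_ij) * h(d_i0)` is time-independent and precomputed once per
simulation, so a 61-community, 120-step run takes a few tens of
milliseconds.

## The synthetic scenario generator

The case study's community map is not published, so `evacsi` generates
seeded synthetic layouts. `synthetic_layout()` draws community positions
uniformly in an annulus around the risk source and labels them by
increasing distance; pairwise distances are Euclidean, so symmetry and the
triangle inequality hold by construction. Per-community populations are
equal by default (the source gives no distribution) with a seeded random
mode as an alternative; types split per the configured proportions (equal
thirds by default).

`tianjin_like_scenario()` pins everything the case study prints: 61
communities, 115,350 residents split equally into three types, communities
1, 10, 27, 31 and 61 at 0.67, 2.06, 4.12, 4.21 and 6.10 km, the parameter
set above, two orders at `t = 0` and `t = 60` h, and 150 evacuated
Impressionable residents of community 1 at time zero. Unpinned radii are
drawn stratified between the pinned ones (so the pinned communities keep
their labels), and community 27 is placed in an otherwise empty angular
sector with only community 41 nearby, emulating its single adjacent
community; listed adjacencies are treated as qualitative placement
guidance only, since the model works on continuous distances, not an
adjacency graph.

What passing tests on these layouts do and do not show: they verify the
*mechanisms* — the S-shaped total curve, the upward increment jump at the
second order, the ordering of type curves, the leading role of the
community nearest the source, and the lag of isolated communities — under a
geometry consistent with the printed facts. They do not reproduce the
numeric demand values of the original case, which depend on the unpublished
map; any published point values tied to that geometry are treated as
non-reproducible reference points, not targets.

## Sensitivity analysis

The model output for sensitivity purposes is the total demand curve sampled
at five instants `t1 < ... < t5`. The source never states the five
instants; the default `(24, 48, 72, 96, 120)` h spans the 120-h case
horizon evenly and is configurable in `sensitivity_config()`. For a
parameter `beta` the sensitivity function is

$$SF(\beta) = \lim_{\Delta\beta \to 0}
  \left\Vert \frac{\Delta O}{O} \right\Vert \Big/
  \left\vert \frac{\Delta\beta}{\beta} \right\vert,
  \qquad
  \left\Vert \frac{\Delta O}{O} \right\Vert =
  \sqrt{\sum_{i=1}^{5}\Big(\frac{O'_i - O_i}{O_i}\Big)^2}$$

approximated by a forward difference with relative step `1e-3` (central
difference available; halving the step changes SF by well under 1% on the
case scenario). The perturbation flows through the *full* pipeline —
including the initial state, which depends on `gamma` — so SF measures the
sensitivity of the whole forecast, not of the dynamics alone. Two analytic
calibrations pin the implementation: a model whose five outputs are
proportional to `beta` has `SF = sqrt(5)` at any `beta`, and a parameter
that does not enter the simulated window (e.g. the second warning piece
with all output times before its issuance) has SF exactly 0.

`sensitivity_scan()` evaluates SF on an even grid and reports the maximum
and mean. Grid points where the relative perturbation is undefined
(`beta <= 0`) are dropped, and ranges whose values violate a construction
constraint are rejected: when scanning `gamma_1`, only `gamma_1` moves
(mirroring the single-factor design), so the grid must stay above
`gamma_2`. Local single-factor analysis is the intended scope; global
(variance-based) methods are out of scope.

## Degenerate inputs and tie-breaks

* Communities with zero population contribute nothing (the `S/Q_j` terms
  are defined as 0).
* Groups at saturation (`S_jk = 0`) have exactly zero derivative.
* A single-piece warning schedule with `a = 0` is a constant forcing; a
  one-community layout has an empty between-community term.
* `aggregate_demand()` computes hourly increments only when the integration
  grid contains the integer hours (any `dt` that divides 1 h); otherwise
  increments are omitted rather than interpolated.

## Known limitations

* Deterministic continuum model: no stochastic or agent-based variant, no
  per-individual network.
* The hazard field is static; a moving threat (e.g. a gas plume) would need
  a time-dependent `f`.
* How individuals map to the three types is an input (the proportions), not
  estimated by the package.
* Warning-message *dissemination* channels are not modelled separately;
  their effect is folded into the shape of `w(t)`.
* Everyone eventually evacuates; interpret long-horizon tails accordingly.
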