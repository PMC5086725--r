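# evacsi

Disaster evacuation demand curves from a metapopulation
Susceptible–Infective model.

## The problem

When a disaster strikes, the authorities need to know not just *how many*
people will evacuate a risk area but *when* they will decide to leave — the
cumulative count of decided evacuees over time is the **evacuation demand
curve**, the key input to evacuation traffic planning. The decision to
evacuate is strongly social: people leave when the people they talk to
leave ("herd behaviour", and the related *shadow evacuation* of low-risk
areas). `evacsi` models this decision process as a contagion, in the spirit
of the classical SI epidemic model, for analysts who want mechanistic,
parameterized demand curves per community and per population type rather
than a hand-picked S-curve.

## The model

Residents of `N` communities are split into three individual types —
Impressionable, Neutral, Standpat — with populations `Q_jk` (community `j`,
type `k`). Each group holds `S_jk` undecided and `I_jk` decided-to-evacuate
people, `S_jk + I_jk = Q_jk`. The decision rate combines four influences:

```
dI_jk/dt = gamma_k [ lambda0 (S_jk/Q_j) I_j                    within-community contagion
                   + (S_jk/Q_j) sum_k sum_{i!=j} I_ik lambda(d_ij) h(d_i0)   between-community contagion
                   + S_jk f(d_j0, t)                           geographic decay
                   + S_jk w(t) ]                               warning degree
```

with `gamma_1 > gamma_2 > gamma_3 > 0` the per-type effective
transformation rates, `lambda(d) = lambda0 * alpha / (sqrt(2 pi) sigma) *
exp(-d^2 / (2 sigma^2))` a Gaussian contact kernel in inter-community
distance, `h(d) = a1 d + b1` an influence weight that makes messages from
evacuees in distant (low-risk) communities more persuasive,
`f(d, t) = a2 / (d^2 + b2 t + 10)` the direct location-driven pressure, and
`w(t)` a piecewise forcing that decays within each warning degree and jumps
upward whenever a stronger order is issued. The `3 N` equations are
integrated by fixed-step forward Euler with clamping to `[0, Q_jk]`;
initial evacuated counts are spread from a single observed anchor count in
inverse proportion to the cubed distance to the risk source and in
proportion to the type's transformation rate.

A dimensionless single-factor **sensitivity function** measures how much
the demand curve responds to each parameter: the curve is sampled at five
instants, and SF is the relative Euclidean norm of the output change
divided by the relative parameter perturbation.

## Worked example

The built-in scenario emulates the published facts of the 2015 Tianjin
explosions evacuation: 61 communities labelled by distance to the explosion
source (0.67–6.10 km), 115,350 residents split equally into the three
types, two evacuation orders at `t = 0` and `t = 60` h, and 150 residents
of community 1 already evacuated at time zero.

```r
library(evacsi)
sc   <- tianjin_like_scenario(seed = 1)
init <- initial_state(sc$layout, sc$params, sc$anchor)
traj <- simulate_evacuation(sc$layout, sc$params, init, dt = 1, horizon = 120)
traj
#> <evac_trajectory: 61 communities, 120 h horizon, dt = 1 h>
#>   evacuated: 724 (0.6%) at t = 0  ->  114113 (98.9%) at t = 120

agg <- aggregate_demand(traj)
subset(agg$increments, hour %in% c(1, 30, 56, 60, 61, 120))
#>     hour        dI d_fraction
#> 1      1  148.7924     0.0013
#> 30    30  941.0284     0.0082
#> 56    56 2193.8174     0.0190
#> 60    60 2129.1613     0.0185
#> 61    61 2509.8565     0.0218
#> 120  120   76.6559     0.0007
```

Only 0.6% of the population has decided to leave at `t = 0`; the hourly
increment then grows from 0.13% to a 1.9% peak around hour 56 and starts to
fall — until the second evacuation order at `t = 60` kicks it back up from
1.85% to 2.18% — after which the curve saturates ("slowly–rapidly–slowly",
the classical S-shape). Per-type and per-community curves are in
`agg$by_type` and `agg$by_community`.

Sensitivity of the demand curve to the within-community contact frequency:

```r
sensitivity_scan("lambda0", c(0, 1), 21, sc$layout, sc$params, sc$anchor)
#> <sensitivity_result: lambda0 over [0.05, 1], 20 points>
#>   maximum SF = 2.4204, average SF = 1.8626
```

The contact frequency is by far the most influential parameter — its SF
peaks above 2 — so demand forecasts hinge on estimating how much people in
the risk area talk to each other.

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "evacsi.R", package = "evacsi"))')" \
    simulate --seed 1 --out-prefix run
```

with subcommands `simulate`, `sensitivity` and `scenario` (see the file
header for flags).

## Documentation

The methods vignette (`vignettes/evacuation-demand-model.Rmd`) describes
the model, its assumptions, the parameter meanings and defaults, the
synthetic-scenario design and the package's numerical choices in detail.
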