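# umwalk

Ultrametric random walks on social trees, for modelling how a disease
spreads through a hierarchically clustered population.

## The problem and the model

Epidemiological compartment models usually treat a population as
well-mixed. `umwalk` instead assumes the population is split into nested
social clusters — country, town, district, workplace, household — and that
preventative measures erect *barriers* between clusters: infection
circulates easily inside a cluster but must "jump over" a barrier to reach
a neighbouring one, and over a stack of barriers to reach a socially
distant one.

The social space is the p-adic tree **Z**<sub>p;n</sub>: every social type
is a vector of `n` base-`p` coordinates ordered by importance, and the
distance between two types is `d(x, y) = n − k`, where `k` is the length of
their longest common coordinate prefix. This distance is an ultrametric
(`d(x,y) ≤ max{d(x,z), d(y,z)}`), clusters are its balls, and the `p^n`
ground-level types carry integer labels `0 … p^n − 1` by reading the
coordinates as base-`p` digits.

A virus performs a continuous-time random walk over this landscape.
Crossing `m` hierarchy levels costs the barrier `Δ_m`; with linearly
growing barriers `Δ_m = mΔ` the hop weight is the Arrhenius factor
`e^{−mΔ}` into each of the `p − 1` sibling clusters at level `m` (shared
uniformly over the cluster's `p^{m−1}` members). The resulting hierarchical
rate matrix diagonalises in closed form: beyond the uniform stationary
mode there are `n` relaxation rates

    ε_m = [(p − R) R^{m+1} − (p − 1) R^{n+1}] / (1 − R),   R = e^{−Δ},

with multiplicities `(p−1) p^{n−1−m}`, and the probability of finding the
walker back at its origin is the exact sum of exponentials

    P(t) = p^{−n} + (1 − 1/p) Σ_{m=0}^{n−1} p^{−m} e^{−ε_m t}.

On its way to the plateau `p^{−n}` this sum traverses a power-law window

    P_I(t) ~ t^{−a},   a = ln(p) / Δ,

which is the model's epidemiological punchline: the probability of getting
infected in a cluster decays as a power law whose exponent is inversely
proportional to the barrier strength, and herd immunity
`P_Im = 1 − P_I ~ 1 − t^{−a}` is approached the more slowly the stronger
the preventative measures. `ln p` is the *spreading entropy* of a uniform
`p`-way split, so equivalently `a = E/Δ`. The mean social distance
travelled by a spreader grows as `⟨d(t)⟩ ~ ln(t)/Δ`.

`umwalk` implements the whole chain: the social space and its ball
partitions, barrier profiles and generators, three independent solution
routes (closed form, analytic spectrum, matrix-exponential oracle), an
exact event-driven stochastic simulator, and the derived observables with
power-law and log-growth fits.

## Worked example

```r
library(umwalk)

tree <- social_tree(p = 2, n = 3)     # 8 social types, labels 0..7
label_dist(tree, 0, c(1, 2, 6))
#> [1] 1 2 3

model <- hop_model(tree, barrier_profile(delta = 1))
solve_master(model, times = c(0, 1, 10, 1e4))
#> # Occupancy trajectory (origin state 0)
#> # A tibble: 4 × 4
#>    time probability subject origin
#>   <dbl>       <dbl> <chr>   <chr>
#> 1     0       1     state:0 0
#> 2     1       0.619 state:0 0
#> 3    10       0.181 state:0 0
#> 4 10000       0.125 state:0 0
```

The walker starts certain to be home (`P = 1`), leaks across the barriers,
and relaxes to the uniform plateau `p^{−n} = 1/8`: in the long run the
virus is equally likely to sit in any social cluster.

On a deep tree the decay exponent is recoverable from the trajectory and
matches `ln(p)/Δ`:

```r
deep <- hop_model(social_tree(2, 12), barrier_profile(delta = 2 * log(2)))
traj <- solve_return_closed(deep, recommended_time_grid(deep, 400))
fit_power_law(traj)
#> Power-law decay fit: P(t) - plateau ~ t^(-a)
#>   a_hat = 0.5104 (se 0.00046), 118 points, t in [70.9, 9.67e+04]
#>   theoretical a = ln(p)/Delta = 0.5000 (rel. err 2.1%)
```

The stochastic simulator reproduces the exact solution to sampling error
(20,000 walkers here):

```r
run <- walk_ensemble(model, times = c(0, 1, 10, 100), walkers = 20000, seed = 1)
empirical_trajectory(run)
#> # A tibble: 4 × 4  (exact values: 1, 0.619, 0.181, 0.125)
#>    time probability
#> 1     0       1
#> 2     1       0.623
#> 3    10       0.183
#> 4   100       0.123
```

Higher-level entry points: `run_exact()`, `run_simulate()`, `run_fit()`,
`run_figures()` (the infection/immunity curves for `Δ = B, 5B, 50B`,
`B = 2 ln p`) and `run_newick()`, all driven by a [`run_config()`] that
round-trips through YAML. A thin command-line wrapper lives at
`inst/cli/umwalk.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "umwalk.R", package = "umwalk"))')" \
    figures --p 2 --n 8 --out out/
```

Results carry `ggplot2::autoplot()` methods and broom-style `tidy()` /
`glance()` views.

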