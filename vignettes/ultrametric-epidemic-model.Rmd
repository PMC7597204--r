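---
title: "Barrier-controlled random walks on social trees: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barrier-controlled random walks on social trees: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umwalk)
```

## The model

`umwalk` treats a population as the leaf set of a regular `p`-ary tree with
`n` levels: a social type is a vector of `n` coordinates in `0..p-1`,
ordered from the most important social factor to the least. Two types that
share their first `k` coordinates are at hierarchic distance `n - k`; this
distance is an ultrametric, its balls are the social clusters, and fixing a
coordinate prefix of length `k` names one of the `p^k` disjoint clusters at
that level.

A virus (or its carrier) performs a continuous-time Markov random walk over
the `p^n` types. Moving between two types at distance `m` means surmounting
the social barrier `Delta_m`; barriers grow strictly with `m`, and the
default linear profile `Delta_m = m * Delta` models a uniform one-step
barrier at every branch point. The hop weight across an `m`-level barrier
is the Arrhenius factor `exp(-Delta_m)`.

The probability `P(C, t)` of finding the walker in cluster `C` is
identified with the probability of becoming infected there, `P_I(C, t)`:
virion concentration in a cluster determines infection risk in it. This
identification is the modelling step, not a theorem; it inherits the
caveats of reading concentrations as risks (fomites, superspreading events)
which the model does not resolve.

### Assumptions

* branching index `p` is the same at every vertex;
* barriers depend on the distance spanned only, not on which clusters are
  involved (a homogeneous tree);
* a single walker; no birth/death of virions, no recovery compartment —
  `P` is a normalised probability flow, not a case count;
* the epidemic's *asymptotic* stage is the target: the model says nothing
  about the early exponential phase.

## Rate normalisation

Hop weights are stated up to a normalisation, and fixing it is the one
genuinely open design point. `umwalk` attaches the weight
`w(m) = c * exp(-Delta_m)` to each of the `p - 1` *sibling clusters*
across an `m`-level barrier and shares it uniformly over that cluster's
`p^(m-1)` members, so the generator's per-pair entry is
`w(m) / p^(m-1)`. Two facts force this choice:

* the relaxation rates then scale as `R^(m+1)` with `R = exp(-Delta)`,
  which combined with the spectral amplitudes `p^-m` produces the decay
  exponent `a = ln(p)/Delta` — the model's central result;
* attaching `exp(-Delta_m)` to each ordered *pair* instead makes the rates
  scale as `(pR)^(m+1)` and the exponent come out as `ln(p)/(Delta - ln p)`,
  which contradicts the target law (and for `p R > 1` changes the physics
  entirely).

With this convention the spectrum is, in closed form for the linear
profile,

\[
\epsilon_m = \frac{(p-R)R^{m+1} - (p-1)R^{n+1}}{1-R}, \qquad m = 0..n-1,
\]

each with multiplicity `(p-1) p^(n-1-m)`; the package checks it against
numeric diagonalisation of the dense generator on every small tree in the
test suite. The return probability is

\[
P(t) = p^{-n} + \Bigl(1-\tfrac1p\Bigr) \sum_{m=0}^{n-1} p^{-m}
e^{-\epsilon_m t},
\]

whose prefactor `1 - 1/p` is fixed by `P(0) = 1`; for `p = 2` it coincides
with `1/p`, which is why two-branch worked examples cannot distinguish the
two. More generally the occupancy of a state at distance `d` from the
origin is

\[
P_d(t) = p^{-n} + \sum_{m \ge d} p^{-m} e^{-\epsilon_m t}
       - \sum_{m \ge d-1} p^{-m-1} e^{-\epsilon_m t},
\]

which is what `solve_master()` evaluates: every quantity — singleton and
ball trajectories, full distance-class occupancies, mean distances — is a
short sum over the `n + 1` distance classes, so trees far beyond any dense
cap (say `n = 40`) cost nothing. The derivation holds for *any* strictly
increasing barrier profile (the eigenvectors do not depend on the rates),
which is why custom profiles go through the same path.

## Tunable parameters

| parameter | meaning | default / rationale |
|---|---|---|
| `p` | branching index: how many subclusters a cluster splits into | 2 in demos — the slowest, "yes/no" society; any integer `>= 2` |
| `n` | hierarchy depth; population is `p^n` | 3 in demos (the worked 8-type tree); 12–14 for scaling fits so the power-law window spans several decades |
| `delta` | one-step social barrier (dimensionless energy) | 1 in demos; figure regimes use `B, 5B, 50B` with `B = 2 ln p`, giving exponents 0.5, 0.1, 0.01 for `p = 2` |
| `rate_scale` | overall rate multiplier `c` | 1 — fixes the time unit; nothing downstream depends on it except a rescaling of `t` |

## Numerical choices

* **Time grids are log-spaced** (`log_time_grid()`), since the phenomena
  span decades; `recommended_time_grid()` places the grid from
  `1e-2 / max(rate)` to `1e2 / min(rate)` so the whole decay is covered.
  Relaxation rates below `1e-290` are dropped from grid planning: they
  underflow double precision and their modes cannot decay on any
  representable grid. For very high barriers (`Delta = 50B`) the usable
  window legitimately sits at `t ~ 1e120..1e270`; doubles carry this
  comfortably and the fits behave.
* **The oracle solver uses symmetric eigendecomposition**, not a series
  expansion of the matrix exponential: the generator is symmetric, and for
  stiff barriers (rates spanning hundreds of orders of magnitude) a series
  is hopeless while the eigenbasis is exact.
* **Plateau subtraction before log-log fits.** On a finite tree `P(t)`
  tends to `p^-n`, not 0; the pure power law is the deep-tree limit.
  `fit_power_law()` therefore fits `log(P - p^-n)` against `log t`, and
  keeps only points whose corrected probability lies in a band (default
  `[10 p^-n, 0.1]`) that excludes both the early transient and the
  saturated tail. Without the correction the fitted exponent is biased
  downward near saturation.
* **Log-growth fits** (`fit_log_growth()`) keep points where the mean
  distance is between 15% and 70% of its uniform-saturation value — the
  same idea: fit where the asymptotic law can hold. The window fractions
  are arguments, not constants.
* **Dense caps.** Dense generators and the brute-force solver stop at 4096
  and 1024 states; they exist for validation, and everything user-facing
  runs on the analytic spectral path with no cap worth mentioning.

## The simulator

`walk_ensemble()` draws exact continuous-time paths: the exit rate is the
same from every state (`(p-1) * sum_m w(m)`), so each walker's event times
are a homogeneous Poisson process — event counts are Poisson, event times
sorted uniforms — and each event hops `m` levels with probability
proportional to `(p-1) w(m)`, landing uniformly in the chosen class.
Destination sampling is done on integer labels with digit arithmetic,
`O(1)` per event rather than `O(p^n)`. There is no time-discretisation
error anywhere, so empirical-vs-exact comparisons are pure sampling-error
tests: the suite holds 20,000-walker ensembles inside 4-sigma binomial
bands of the exact solution, point by point.

All randomness flows from one `set.seed(seed)` at entry; runs are
reproducible bit-for-bit on a fixed platform. The ensemble is an ensemble
of *independent* walkers — it estimates the same probability flow the
solver computes exactly, and is not a claim that virions are conserved
particles.

## What the test problems do and do not show

The suites run at desk scale: exhaustive checks on trees up to 81 states,
oracle equivalence on `(p, n)` up to `(2, 4)`, scaling fits at `n = 12`
(exponent, recovered within ~2% where 15% is required) and `n = 14`
(mean-distance slope within ~3% of `1/Delta`), and 20,000-walker
ensembles. These verify the mathematics of the model, including its
asymptotic laws, on exactly the landscape the model postulates. They do
not validate the model *against epidemic data*: coordinates are abstract,
barriers are scalar free parameters, and no procedure here estimates `p`
or `Delta` from observed case curves.

## Known limitations

* Vertex-dependent branching and cluster-dependent barriers are out of
  scope; both break the distance-only rate structure the closed form rests
  on.
* Time-dependent barriers (policies changing mid-epidemic) are not
  modelled.
* The spreading-entropy exponent `E/Delta` for a *nonuniform* split is
  exposed (`entropy_exponent()`) but flagged as conjectured: the walk that
  would realise it needs cluster-dependent rates, which the model does not
  define.
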