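# flocksim

Spatially explicit, asynchronous agent-based simulation of collective
motion with **stochastic choice of interaction neighbours**, plus the
analysis layer needed to study group cohesion: ε-graph clustering,
windowed attraction-interaction networks, and mean-field SDEs for the
polarization order parameter.

## The problem

Classic flocking models (Vicsek, Boids, Couzin) assume each organism
averages over *all* neighbours in a zone. Empirical studies of fish and
bats suggest organisms often interact with a *single* neighbour at a
time, chosen roughly at random from the few they perceive. That raises a
concrete question for movement ecology: if each of N organisms perceives
only its K nearest visible neighbours and, at exponentially distributed
random times, aligns with or moves towards k of them chosen uniformly at
random, when does the group stay together?

`flocksim` is for researchers in collective animal behaviour who want a
reproducible, scriptable implementation of that model family:

* **stochastic pairwise** interaction: `k = 1` (one random neighbour out
  of K; `K = 1` is the nearest-neighbour special case),
* **local averaging** interaction: `k = K` (topological Vicsek/Boids
  analogue).

## The statistics at its core

* **Cohesion parameter `C`** — agents are partitioned at every snapshot
  into ε-clusters (connected components of the graph linking pairs at
  distance < ε); `C` is the time-averaged fraction of the group in the
  largest cluster, and `Nc` the mean number of clusters. `C = 1` means
  the group never fragmented.
* **Network parameter `Np`** — over disjoint windows of length
  `t_w = ε / s0`, a directed edge i → j records an attraction
  interaction of i towards j; sub-groups are the mutually reachable
  classes (strongly connected components) of that graph, and `Np` is the
  window-averaged largest sub-group fraction.
* **Saturation threshold `K*/N`** — the smallest K/N at which the
  replicate-averaged `C(K)` reaches 95% of its value at `K = N − 1`.
* **Polarization SDEs** — Euler–Maruyama integration of
  `dm/dt = −am + g(m) η(t)` (pairwise copying; order is noise-induced)
  and `dm/dt = −am + h(1 − m²)m + g(m) η(t)` (averaging-type), with
  multiplicative noise `g(m) = sqrt((c_eff (1 − m²) + a)/N)`.

## Worked example

```r
library(flocksim)

p <- flock_params(N = 30, K = 10, k = 1)   # pairwise: one random neighbour of 10
traj <- simulate_flock(p, t_end = 100, seed = 1)
traj
#> <flock_trajectory> N = 30, t_end = 100, 201 snapshots, 14961 events (seed 1)

glance(cohesion_parameter(traj))
#> # A tibble: 1 × 4
#>       C Nc_mean epsilon n_samples
#>   <dbl>   <dbl>   <dbl>     <int>
#> 1 0.879    2.55       2       161

glance(network_parameter(traj))
#> # A tibble: 1 × 3
#>      Np   t_w n_windows
#>   <dbl> <dbl>     <int>
#> 1 0.425     2        40
```

With `K = 10` of `N = 30` (a third of the group), a group interacting
with *one random neighbour at a time* keeps 88% of its members in a
single ε-cluster on average (`C = 0.879`), and within each window of
`t_w = 2` time units the attraction network alone mutually connects 42%
of the group (`Np = 0.425`). Rerun with `K = 1` and `C` collapses — the
group shatters into clusters of two or three.

The mean-field layer:

```r
tr <- simulate_sde(sde_params(a = 1, c = 1, N = 50), t_end = 500, seed = 1)
glance(tr)
#> # A tibble: 1 × 9
#>   model        a     c     h     N    mean_m  var_m mean_abs_m      n
#>   <chr>    <dbl> <dbl> <dbl> <int>     <dbl>  <dbl>      <dbl>  <int>
#> 1 pairwise     1     1     0    50 -0.000820 0.0205      0.115 400001
```

The stationary variance 0.0205 sits on the Ornstein–Uhlenbeck prediction
`(c + a)/(2aN) = 0.02`: polarization fluctuations in the pairwise model
are a finite-size, noise-induced effect.

Sweeps over `(N, K, replicates)` are driven by a YAML config or
`flock_config()`, via `run_sweep()` / `summarise_sweep()` /
`estimate_saturation_threshold()`, with `autoplot()` methods for every
result type. A command-line front end (`inst/cli/flocksim.R`) exposes
`simulate`, `analyze`, `sweep`, `sde` and `fixtures` subcommands.

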