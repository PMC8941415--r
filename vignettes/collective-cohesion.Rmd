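---
title: "Stochastic neighbour choice and group cohesion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic neighbour choice and group cohesion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flocksim)
```

## The scientific question

Classic flocking models let every agent average the headings and positions
of all neighbours within a metric zone. Empirical work on fish schools and
bat swarms suggests something far simpler: an organism often interacts with
a *single* neighbour at a time, chosen more or less at random from the few
it can perceive. `flocksim` implements a spatially explicit, asynchronous
agent-based model built around that idea, together with the analysis
machinery needed to ask: *how much neighbourhood does an organism need for
the group to stay together?*

Each of the $N$ agents perceives its $K$ nearest neighbours (topological,
not metric, distance) inside a visual field, and at exponentially
distributed random times interacts with $k$ of them chosen uniformly at
random. Two regimes bracket the behaviour: the *stochastic pairwise*
interaction ($k = 1$) and the Vicsek-like *local averaging* interaction
($k = K$).

## Model

An agent $i$ carries position $\mathbf{x}_i$, speed $s_i$ and heading
$\angle e_i$, with kinematics $\dot{\mathbf{x}}_i = s_i \mathbf{e}_i$.
Events arrive by a Gillespie scheduler: the total propensity is
$\Lambda = N(r_p + r_c + r_s)$, waiting times are $\mathrm{Exp}(\Lambda)$,
the focal agent is uniform, and the event type is proportional to its rate.
This is equivalent to independent per-agent exponential clocks and
guarantees exactly one behavioural interaction at a unique time.

The behavioural rules:

* **Alignment** (rate $r_p$): copy the heading and speed of the chosen
  partner; with $k > 1$, use the circular mean heading and the mean speed.
* **Attraction** (rate $r_c$): head towards the partners' centroid at
  speed $s_0 d / \varepsilon$ (clamped to $[s_{\min}, s_{\max}]$), where
  $d$ is the distance to the centroid. The linear law is the simplest
  monotone choice for "speed dependent on distance"; the reference scale
  is the cluster scale $\varepsilon$ so that an agent one cluster-width
  away closes in at its cruising speed.
* **Spontaneous turn** (rate $r_s$): heading perturbed by a wrapped
  normal with variance $\sigma_a^2$; speed redrawn from a truncated
  normal around $s_0$ with variance $\sigma_s^2$.
* **Collision avoidance**: any agent with another within $d_c$ rotates
  away from its nearest offender at angular speed up to
  `avoid_turn_rate` and slows by `avoid_slow_factor`. We treat this as a
  continuous control acting during motion (applied each micro-step), not
  as a scheduled event, because it describes *how* agents move rather
  than a discrete decision.

Between events the world advances ballistically in micro-steps
$\delta t = \min(0.01,\; \varepsilon / (10\, s_{\max}))$, small enough that
an agent moves a small fraction of both the avoidance radius and the
cluster scale per step. The `minimal = TRUE` variant reduces the model to
constant-speed point particles with omnidirectional perception and no
avoidance.

## Quantifying cohesion

At every snapshot we partition agents into $\varepsilon$-clusters: connected
components of the graph linking pairs strictly closer than $\varepsilon$
(density-based clustering with the core-point minimum reduced to chaining).
The **cohesion parameter** $C$ is the time-averaged fraction of the group
in the largest cluster; $N_c$ is the mean cluster count. $C = 1$ means the
group never fragmented. Ties at exactly $\varepsilon$ are disconnected
(strict inequality), which only matters for constructed configurations.

The **attraction interaction network** is built over disjoint consecutive
windows of length $t_w = \varepsilon / s_0$ — the time an agent needs to
cross one cluster width at cruising speed. Within a window, a directed
edge $i \to j$ records that $i$ exhibited an attraction interaction
towards $j$; the graph is directed because neighbour choice is one-sided.
From the adjacency $A$ we form the reachability matrix (transitive
closure, with self-reachability on the diagonal so singleton classes are
well defined) and partition agents into mutually reachable *sub-groups*
(strongly connected components). The **network parameter** $N_p$ is the
window-averaged largest sub-group fraction. Disjoint rather than sliding
windows keep the per-window samples non-overlapping so their mean is well
defined.

## Mean-field order-parameter SDEs

For the polarization order parameter $m \in [-1, 1]$ (scalar form), two
Langevin models contrast pairwise copying with averaging-type
(higher-order) interactions:

$$\frac{dm}{dt} = -a m + g(m)\,\eta(t), \qquad
\frac{dm}{dt} = -a m + h(1 - m^2)m + g(m)\,\eta(t),$$

with multiplicative noise $g(m) = \sqrt{(c_\mathrm{eff}(1 - m^2) + a)/N}$,
$c_\mathrm{eff} = c$ for pairwise and $c + h$ for the higher-order model.
In the pairwise model the drift is purely relaxing and order is
*noise-induced* (a finite-size effect: fluctuations scale as
$1/\sqrt{N}$); the higher-order drift has stable roots at
$\pm\sqrt{1 - a/h}$ for $h > a$ and holds order deterministically.

Two readings of the multiplicative noise factor are defensible a priori,
$(1 - m^2)$ and $(1 - |m|)^2$; we adopt $(1 - m^2)$ with a $1/N$
prefactor inside the radical, the form consistent with (i) noise
vanishing at full order when $a = 0$ and (ii) fluctuations vanishing as
$N \to \infty$. The alternative reading is available behind the
`radicand` argument of `sde_diffusion()` / `simulate_sde()` so the two
can be compared; the choice is isolated in that one function.

Integration is Euler–Maruyama with default step $10^{-3}$, clamping to
$[-1, 1]$ after each step (a reflecting scheme was rejected for
simplicity; at the default step the clamp binds rarely except at extreme
parameters). A heuristic warning fires when
$dt \ge 1/(2(a + c + h))$.

## Default parameters and calibration

The model's rates and noise variances are not pinned down by first
principles, so the package's defaults were calibrated once, against the
qualitative regime this model family is built to study, and then
frozen:

* break-up of an $N = 30$ group under nearest-neighbour-only interaction
  ($K = k = 1$) into small clusters (median size 2–3);
* cohesion $C$ rising with $K$ and saturating near $K/N \approx 0.3$;
* a network parameter $N_p$ that rises monotonically with $K$.

The calibrated defaults are $r_p = 1$, $r_c = 1$, $r_s = 3$ (1/time),
$\sigma_a^2 = 1$ rad², $\sigma_s^2 = 0.01$, $s_0 = 1$ in
$[s_{\min}, s_{\max}] = [0.1, 2]$, $\varepsilon = 2$, $d_c = 0.2$,
visual field $300^\circ$ (a $60^\circ$ blind cone behind), avoidance turn
rate $\pi$ rad/time and slow factor $0.5$. Two choices deserve comment.
First, the spontaneous-turn channel must be strong relative to the
interaction channels ($r_s = 3$, $\sigma_a^2 = 1$): with weak wandering,
nearest-neighbour clusters of 4–6 agents are dynamically stable and the
group never fragments down to the pair scale. Second, the cluster scale
$\varepsilon = 2$ (in units of the distance an agent cruises per unit
time) both sets the window $t_w = 2$ — long enough that an agent has on
average two attraction interactions per window, putting the interaction
network near its connectivity transition where $N_p$ is informative — and
keeps the $\varepsilon$-clustering robust (doubling $\varepsilon$ changes
$C$ by less than 0.05 on cohesive runs). All values are exposed in
`flock_params()` and the sweep configuration.

Initial conditions place agents uniformly in a disc of radius
$\varepsilon\sqrt{N}$ (constant initial density across $N$), with uniform
headings and speed $s_0$. The first 20% of every run is discarded from
all time-averaged statistics.

## Numerical and degenerate-case choices

* Angles live in $(-\pi, \pi]$; the wrap maps the boundary to $+\pi$.
* Distance ties in topological ranking break by ascending agent id, so
  ranking is deterministic and testable.
* Agents at identical positions are mutually visible at distance 0 and,
  when colliding, turn counter-clockwise (a fixed deterministic rule).
* A zero-resultant circular mean (e.g. an antipodal heading pair) is
  undefined; the simulator then keeps the current heading.
* An agent already at its partners' centroid keeps its heading and
  cruises at $s_0$.
* Replicate $r$ of a sweep uses seed `base_seed + r - 1`; every run is
  bit-reproducible from its seed.

## What the synthetic generators do and do not show

`make_fixture()` builds deterministic configurations (line, two blobs,
ring) and synthetic event logs (full directed cycle per window; cycles
confined to two halves) whose cluster and sub-group structure is known by
construction. These fixtures validate every analysis stage — clustering,
adjacency, reachability, sub-groups, windowing — independently of the
simulator. They do not emulate measurement noise, missing detections, or
the smooth trajectories of real organisms, so passing them certifies the
*analysis arithmetic*, not the applicability of the model to any given
empirical data set. Likewise the simulator itself is a theoretical model:
agents are homogeneous, the domain is unbounded and two-dimensional, and
perception is a clean geometric field of view without occlusion.

## Problem sizes

The packaged experiments run at desk scale: group size $N = 30$, sweeps
over $K \in \{1, 2, 5, 8, 10, 15, 29\}$, horizon $t_{\mathrm{end}} = 200$
with snapshots every $0.5$, and 10 replicates per cell. These sizes were
chosen so a full sweep completes in minutes on a single core while still
resolving the saturation of $C$ and the $N_p$–$C$ relationship; the
estimator interfaces accept larger configurations unchanged.

## Known limitations

* The saturation threshold is operationalized as the smallest $K/N$ with
  $C(K) \ge 0.95\, C(N-1)$, linearly interpolated between sampled $K$;
  the 0.95 factor is configurable and the estimate inherits the coarse
  $K$ grid's resolution.
* With 10 replicates the replicate-mean curves carry visible sampling
  error; the estimator is deliberately tolerant (interpolation, not
  fitting).
* $N_p$ counts agents with no successful attraction interaction in a
  window as singleton sub-groups, so $N_p$ systematically underestimates
  spatial cohesion for sparse interaction regimes (small $K$, small
  groups) — which is exactly the regime where the network and spatial
  views of cohesion genuinely differ.
* The SDE layer treats $m$ as a scalar projection; the full 2-D
  polarization vector is out of scope.
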