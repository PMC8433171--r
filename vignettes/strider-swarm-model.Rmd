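---
title: "An individual-based swarm model of a water-strider population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An individual-based swarm model of a water-strider population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striderSwarm)
```

## The model

`striderSwarm` simulates a group of water striders (*Gerris*) of
heterogeneous body size living on a bounded patch of water surface
`[0, Lx] x [0, Ly]`. Each animal `j` carries a position `r_j`, a velocity
`v_j` and a mass `m_j`, and obeys damped Newtonian dynamics

    m_j dv_j/dt = F_j - eta_j v_j,      eta_j = eta0 * m_j^(1/3),

where `F_j` collects four behavioural forces:

* **Short-range repulsion** (private territory): a Gaussian pair force
  `B_rep,j (r_j - r_k) exp(-|r_j - r_k|^2 / R_jk^2)`.
* **Weak long-range attraction** (tendency to aggregate): the same kernel
  with opposite sign, smaller amplitude and a larger radius.
* **Soft boundary walls**: four exponential walls
  `B_bound exp(-d/R_bound)` pushing inward, with `B_bound` far above the
  pair amplitudes and `R_bound` far below the equilibrium spacing.
* **Food attraction**: each deposited portion pulls animals with a
  Gaussian force of amplitude `B_food0 * m_j^(2/3)` and radius `R_food`.

A periodic **wave of fear** can be enabled: during scheduled windows an
extra exponential repulsion of amplitude `B_wave * m_j^(2/3)` and decay
length `R_wave >> R_bound` acts from the dangerous shore (`x = 0`),
emulating synchronized escape from a disturbance on the bank.

Interaction radii are properties of a pair — the mean of the partners'
body-length scales, `R_jk = R0 (m_j^(1/3) + m_k^(1/3)) / 2` — while
amplitudes are properties of the responding animal,
`B_j = B0 m_j^(2/3)`. These are behavioural response forces rather than
contact mechanics: both partners read the same signal (the shared Gaussian
kernel) but each responds with its own strength. For equal masses the pair
force is exactly antisymmetric and injects no net momentum. For unequal
masses the stronger animal responds more strongly; combined with
`eta ~ m^(1/3)` every self-generated force produces drift speeds scaling
as `m^(1/3)`, which is what makes the big animals the fast ones — the
alternative convention (amplitudes symmetric in the pair) makes *light*
animals the fastest responders and we found it incompatible with the
velocity–size ordering the model is meant to reproduce.

Balancing repulsion against attraction for two equal animals gives the
equilibrium spacing

    R_min = sqrt( log(B_rep/B_att) / (1/R_rep^2 - 1/R_att^2) ),

implemented in `equilibriumDistance()`; `R_min(m) = R_min(1) m^(1/3)`.
Groups pack at distances close to `R_min`, separated by voids, and the
long-run histogram of nearest-neighbour distances peaks at `R_min`.

## Demography and foraging

Four stochastic procedures run between integration steps, in a fixed,
documented order (consumption, cull, recruitment, deposition; all draws
from one RNG stream so a run is reproducible from `(params, seed)`):

* **Recruitment.** Once per step, with probability `p_birth`, a new animal
  appears at a uniform-random position, at rest, with mass uniform on
  `m_s ± m_s_spread`. Uniformity was chosen for its bounded support and
  trivial verification; the model only requires "small, randomly spread".
* **Removal.** An animal reaching either critical mass (`<= m_min` or
  `>= m_max`, inclusive — reaching the critical size is fatal) leaves the
  population. Both kinds are tallied (starvation vs. completed growth).
* **Food deposition.** Once per step, with probability `p_food`, a portion
  of capacity `q_food` lands at a uniform-random position.
* **Consumption.** Every animal strictly within `R_food_thres` of a
  portion eats from its *nearest* portion only (ties to the lowest portion
  id) with demand `mu * m_j * dt` — consumption proportional to
  accumulated mass, so large animals eat more. If a portion cannot cover
  the combined demand it is split proportionally to demand and exactly
  emptied; empty portions disappear. Afterwards every animal loses the
  fraction `lam * dt` of its mass (stored-energy loss). Assimilation
  efficiency is 1, so with `lam = 0` food mass is conserved exactly.

The phase order means a newborn cannot die in its birth step, and a
starving animal gets to eat before it is judged.

## Numerical choices

The integrator is a semi-implicit (damped) Euler scheme,
`v <- (v + dt F/m) / (1 + dt eta/m)`, `r <- r + dt v`, unconditionally
stable in the damping term; the Gaussian kernels are smooth enough to
tolerate the default `dt = 0.01` (about 1/100 of the smallest damping time
`m/eta`). Free-decay and exponential-growth closed forms are reproduced to
better than `1e-3` at the defaults. Pair kernels fall below machine
precision beyond six radii, so the compiled engine skips those pairs; the
result is identical to the exact sum at double precision. Force evaluation
is the plain `O(N^2)` sum (`N ~ 10^2`).

## Default parameters

The model is formulated in nondimensional units: lengths of order one
body spacing, times of order one recruit damping time (`eta0 = 1`,
`m_s = 1`), masses in recruit masses. No published parameter values exist
for this system, so the defaults were fixed once, by calibration to the
qualitative regime the model is meant to inhabit, and then frozen:

* `B_repuls0 = 10, R_repuls0 = 0.7, B_attract0 = 0.2, R_attract0 = 1.4`
  (`R_min(1) = 1.60`). Two constraints drive this choice. First, a
  Gaussian repulsion has a *finite* maximum (`0.43 B R`), so a cluster
  collapses to zero spacing whenever the summed attraction exceeds it;
  stable `R_min`-spaced groups need stiff, short repulsion and weak,
  short attraction. Second, attraction must stay gentle enough that
  newborns falling into a cluster are not violently accelerated.
* Arena `20 x 20` with `N0 = 100`: moderate coverage (each animal's
  territory `~pi (R_min/2)^2` fills about half the arena), leaving voids.
* `mu = 0.2, lam = 0.011, p_birth = 0.006, p_food = 0.013, q_food = 2`,
  mass window `(0.5, 6)`: a balanced, quasi-stationary population of
  roughly 200 animals with both removal routes active and the small class
  dominant. The balance is genuinely delicate — a 10% change in `lam`
  can tip the population from a food-rich plateau into decline, which is
  the behaviour the model predicts for a real population near its
  resource limit.
* Fear-wave scenario: `B_wave = 100, R_wave = 8`, five time units every
  fifty. The wave must overpower the wall (`B_wave > B_bound`) and reach
  deep into the arena (`R_wave >> R_bound`); the schedule is periodic
  (the regular variant accumulates statistics fastest) and frequent
  enough that the food piling up near the dangerous shore does not lure
  the population back to a uniform time-average between waves.

Size classes default to equal thirds of the mass window; critical-mass
comparisons are inclusive; histogram bins default to `R_min/10` (NND) and
`(m_max - m_min)/40` (mass).

## What the experiments show — and what they do not

`nndModeExperiment()` disables demography and foraging, relaxes 100
equal-mass animals for 5x10^4 steps and folds every snapshot's
nearest-neighbour distances: the histogram mode falls within one bin of
the analytic `R_min`. `convergenceExperiment()` starts populations of
only-small and only-large individuals and shows their final-quarter mass
distributions agree (two-sample KS distance well below 0.15, identical
modes) — the stationary size distribution forgets its initial condition.
`speedMassExperiment()` pools the stationary snapshots of those six runs
and bins mean speed by mass; bins holding fewer than 50 of the ~3x10^5
pooled animal-snapshots are reported as missing because a mean over a
handful of autocorrelated track points estimates nothing. The Spearman
rank correlation across the remaining ~30 bins is about 0.69: speed
increases with size, though not perfectly monotonically — the very largest
animals are oversampled while parked on food portions (they are the ones
finishing their growth), a genuine feature of the model, not noise.
`waveExperiment()` shows the time-averaged population shifted away from
the dangerous shore (near/far quarter ratio ~0.8) while uneaten food
accumulates there, anticorrelating the two profiles (r ~ -0.55).

The synthetic camera module (`synthesizeScene()`, `reduceDetections()`)
emulates the video-reduction pipeline: known field positions are projected
through the inverse perspective transform, pixel noise is added, and the
reduction recovers positions, lengths and two-axis ellipsoid volumes
(`V = pi/6 L W^2`, thickness taken equal to width up to a configurable
factor). It emulates geometry and detection noise only — not occlusion,
segmentation error, tracking failures or surface ripple distortion — so
passing tests validate the reduction mathematics, not the upstream video
processing.

These experiments run at reduced problem sizes (10^5 steps, a few
hundred animals) chosen to make the statistics stable while keeping a
full replication cheap; they probe the model's internal consistency and
its qualitative agreement with field observations, not quantitative
parameter estimates for any real pond.

## Known limitations

* No wing/sex dimorphism, no discrete instars, no behavioural types; size
  is the only individual trait.
* No hydrodynamic or capillary-wave signalling between individuals;
  predation appears only implicitly through the starvation threshold and
  the wave forcing.
* Food is point-like, static and non-degrading; portions are eaten from
  the nearest-portion rule rather than a shared-radius competition.
* One recruitment and one deposition trial per step (rates below
  `1/dt`); both are global, not per-capita.
* The momentum of the pair interaction is conserved only for equal-mass
  pairs, by design (behavioural forces of self-propelled animals).

## A worked example

```{r example, eval = FALSE}
p <- simulationParams(seed = 42)
rec <- runSimulation(p, nSteps = 20000, recordEvery = 500)
rec
counters(rec)[seq(1, 41, by = 10), c("t", "N", "N_c1", "N_c2", "N_c3")]

acc <- foldRun(rec, histogramAccumulator(nndBinEdges(p)), "nnd",
               tMin = 100)
histogramMode(acc)          # close to equilibriumDistance(1, p)
```
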