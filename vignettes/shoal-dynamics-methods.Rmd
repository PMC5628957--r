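---
title: "Methods: simulating and analysing shoals of consistently different individuals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing shoals of consistently different individuals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoaldyn)
```

`shoaldyn` addresses a question from collective animal behaviour: how do
consistent inter-individual differences — "personality" in the loose sense —
shape the structure, leadership, movement dynamics and foraging performance
of small fish shoals?  The package has two halves that mirror how such a
study is actually done: a self-propelled-particle model whose agents differ
consistently in intrinsic speed and goal-orientedness, and a complete
trajectory-analysis pipeline that works identically on simulated output and
on empirical tracking tables (per-frame x/y positions of tagged fish at a
known frame rate and body length).

## The agent-based model

Each agent *i* carries a position, a unit direction, a constant intrinsic
speed and a constant goal-orientedness weight $\omega_i$.  Speeds are drawn
once per simulation from a Gaussian (mean `speed_mean`, s.d. `speed_sd`,
non-positive draws resampled) or from a Gamma distribution for the
right-skewed case; $\omega_i$ is Gaussian floored at zero.  Holding these
constant within a run is the point of the model: every group-level pattern
must emerge from fixed individual differences, not from state changes.

Per time step $\Delta t$, each agent:

1. **Social vector.** If any neighbour sits within the repulsion radius
   $r_r$, the desired social direction is the sum of unit vectors pointing
   away from those neighbours, and nothing else is considered (collision
   avoidance has priority; it is omnidirectional).  Otherwise the agent
   aligns with the headings of neighbours in the orientation shell
   ($r_r < d \le r_o$) and is attracted towards neighbours in the
   attraction shell ($r_o < d \le r_a$); each shell sum is normalized and
   the two are added.  Orientation and attraction are restricted to a
   field of perception of $\alpha = 270^\circ$ (a $90^\circ$ blind area
   behind the agent).
2. **Goal reconciliation.** The desired direction is
   $\hat{d}_i = \widehat{\hat{s}_i + \omega_i \hat{g}_i}$, where
   $\hat{g}_i$ points along the current motion (inertia) unless a
   still-provisioned food patch lies within the cue radius $r_c$, in
   which case it points at the nearest such patch.  A zero resultant
   keeps the previous heading.
3. **Noise and turn cap.** $\hat d_i$ is rotated by a wrapped-Gaussian
   angle (s.d. `noise_sd`), and the agent turns towards the result along
   the shorter arc by at most $\psi_{max}\Delta t$ degrees.
4. **Displacement.** $c_i \mathrel{+}= \hat v_i\,|v_i|\,\Delta t$.  The
   free-schooling arena is a periodic box of side $A$ (neighbour vectors
   use the minimum-image convention; returned trajectories are unwrapped
   so finite differences never see the seam).  The foraging arena is a
   disc of diameter $A$ with a repelling edge zone in which the desired
   direction is replaced by the unit vector towards the arena centre.
5. **Feeding.** An agent over a provisioned patch consumes one item with
   probability $f$ per step; items decrement atomically (agents in index
   order), and every consumption is logged as (time, agent, patch).

Defaults (`sim_config()`): $A = 500$, $r_r = 1$, $r_o = 6$,
$r_a = \infty$, $\alpha = 270^\circ$, $\psi_{max} = 60^\circ$ per time
unit, $\Delta t = 0.1$, `speed_sd` 0.1, `omega_sd` 0.01, $r_c = 30$, 3
patches of radius 10 with 50 items each, $f = 0.001$.  One length unit
is roughly one body length and one time unit one second, which is how
`sim_to_mm()` converts model output to the empirical units (mm at
40.6 mm body length) expected by the classification thresholds.
Free-schooling runs last 2000 steps with snapshots every 200; foraging
runs 10,000 steps with snapshots every 500.  Within the explored ranges
(speed 0.1–2.0, $\omega$ 0.01–0.1) the package defaults are mean speed
1.0 and mean $\omega$ 0.05, the approximate midpoints.

Three parameter choices were genuinely open:

* **Heading-noise s.d.** is not in the parameter table of the study
  design this model follows; we use $0.05$ rad ($2.86^\circ$), the
  customary value in this model lineage.
* **Boundary-zone width** ("a narrow zone near the edge") is 4% of the
  arena radius, configurable.
* **Sign conventions.** As printed in the source material's equations,
  the orientation and attraction sums carry minus signs that would make
  agents flee one another and contradict the cohesive shoals those
  equations are meant to produce; the package uses the attractive signs
  of the model lineage.  `literal_signs = TRUE` restores the printed
  signs for auditability.

**Gamma speeds.** The right-skewed speed condition is described as having
a mean within the explored speed range and a variance identical to the
Gaussian case, but the printed parameters ($k = 0.4$, $\theta = 0.05$)
give mean 0.02 and variance 0.001 — neither holds, and at mean speed 0.02
the agents barely move and front/back structure degenerates.  $k = 4$,
$\theta = 0.05$ satisfies both stated constraints exactly (mean 0.2,
variance 0.01), so we treat the printed shape as a typo: `sim_config()`
keeps the printed defaults and exposes both parameters, while the
robustness checks of the speed→front assortment under skewed speeds run
at $k = 4$, $\theta = 0.05$.

## Trajectory analysis

Coordinates are x-right, y-"north"; headings are degrees clockwise from
+y in $(-180, 180]$, so $\psi = \mathrm{atan2}(u, w)$ from velocity
components $(u, w)$.  (The printed heading equation in the source
transposes the atan2 arguments, contradicting its own prose and the
group-frame transform; only relative angles and $|\gamma|$ are affected
downstream, so results are convention-invariant.)  Velocity is the
forward finite difference of (optionally Savitzky–Golay smoothed,
window 15, order 3) positions; acceleration the central difference;
turning speed the wrapped heading difference per unit time.  Edge frames
of each stencil and zero-speed headings are NA, never extrapolated, and
all downstream statistics respect the NA mask.  On circle fixtures at
24 fps the discretization error of all three quantities is below 0.1%,
an order of magnitude inside the 1% oracle tolerance used in the tests.

Group-referenced metrics follow the standard definitions: per-fish
nearest-neighbour distance; centre distance to the group centroid; the
group-frame transform $\sigma = \mathrm{wrap}(\delta - \psi_c)$,
$(x', y') = CD\,(\sin\sigma, \cos\sigma)$ with "front" meaning strictly
$y' > 0$; cohesion as the mean pairwise distance (the ordered-pair
double count reduces to the unordered mean, which is what we compute);
and polarization $\rho = \frac{1}{n}\lVert\sum_i(\sin\psi_i,
\cos\psi_i)\rVert$.  Frames where the centroid moves slower than
$10^{-6}$ length units/s have no defined travel direction and are
excluded from front-occupancy denominators.  Centre-distance ranks run
1 (most central) to n (most peripheral) with mean ties.

### Schooling classification

A frame is *schooling* when the group is cohesive
(IID $\le 160$ mm), moving (centroid speed $\ge 0.5$ BL/s), aligned
($\rho \ge 0.6$) and neither split nor carrying an outlier; thresholds
are boundary-inclusive.  The outlier/split rule links fish within 4 BL
(the same proximity cut-off as the leadership filters) and inspects the
connected components: one isolated fish is an outlier, two or more
non-trivial components a split.  The robustness scan re-evaluates the
schooling proportion under all 125 combinations of polarization
0.4–0.8, speed 1.0–3.0 cm/s and cohesion 100–220 mm — 124 alternatives
to the primary set, whose 0.5 BL/s maps to the 2.0 cm/s grid point at a
40.6 mm body length — and correlates each with a per-trial covariate
(Spearman; asymptotic p by default, exact permutation available for
small trial counts).

### Leadership

For each dyad, fish *i*'s series at *t* is compared with fish *j*'s at
$t + \tau$ for $\tau \in [-72, 72]$ frames (3 s at 24 fps): Pearson
correlation of speeds (raw by default; first-differencing is a switch)
or the mean cosine of the heading difference, which is circular-safe
where Pearson on wrapped angles is not.  Frames enter only when the
pair is closer than 4 BL and both fish exceed 1 BL/s (strict
inequalities), and a lag needs 240 eligible overlapping frames (10 s)
to be defined; ties at the peak resolve towards the smaller |lag|.
Positive $\tau^*$ means *i* precedes *j*; the network draws an edge
from the earlier to the later fish of each non-zero dyad, weighted by
the mean delay in seconds.  Whether the "mean time point of the
maximum" is averaged over windows or trials was left open in the source
material; both modes exist, with 30 s windows at 50% overlap when
windowing is requested.

### Foraging and behavioural scores

Patch discovery uses point-in-vicinity: within 30 mm of the patch
boundary (square patches by half-width, disc patches by radius) or over
the patch, first arrival per patch, ties within a frame broken by fish
order.  Cover occupancy approximates "at least half the body out of
cover" by the tracked point being outside the cover disc — a documented
approximation, since point tracks carry no body extent.  Excursions are
maximal runs of frames with the group centroid outside the cover disc;
leaving order ranks fish by first out-of-cover frame within each
excursion.  Exploration and social-proximity scores are cohort min–max
scalings (the only normalization that guarantees the stated [0, 1]
bounds) of, respectively, the mean proportion of time out of cover and
the square-root-transformed, inverted mean shoal distance; relative
scores subtract the group-mates' mean.

Because full depletion of the simulated provisioning (150 items at
$f = 0.001$) is unreachable within a 10,000-step run — five agents
parked on patches for an entire run eat about 50 items in expectation —
depletion speed is summarised as the survival-style latency to the 15th
consumed item (the experimental per-trial provisioning), censored at
run end.  `depletion_latencies()` keeps explicit censoring flags so the
output feeds survival models directly.

## What the synthetic data does and does not show

The parametric fixtures (lines, circles, delayed followers) have
closed-form kinematics and planted lead–follow delays; they are the
oracle surface for the analysis functions, and passing them shows the
estimators are correct, not that real fish behave like the model.  The
simulator emulates the study conditions — groups of 5 (optionally 20),
heterogeneous speeds and $\omega$, periodic free-schooling arena,
circular foraging arena with three patches — but it is deliberately
minimal: no body shape or size, no occlusions or tracking noise, no
satiation, learning or state-dependent speed, and a feeding process
reduced to a Bernoulli rate.  Results on empirical tracking tables
therefore inherit only the pipeline's correctness, none of the model's
conclusions.

Two model findings deserve emphasis because the tests encode them:

* **Faster agents lead.**  Across 100 seeded 5-agent free-schooling
  replicates, the Spearman correlation between intrinsic speed and
  front-position fraction is positive in ~98% of replicates.
* **Peripheral positioning does not emerge at n = 5.**  In a five-agent
  shoal the fastest agent sits at the front *edge* and the slowest at
  the back *edge*; both are peripheral, so speed vs centre distance is
  U-shaped and the correlation averages zero (this holds across every
  variant we probed: higher $\omega$, larger speed s.d., raw-sum zone
  combination, post-transient analysis).  At n = 20 the effect appears
  (positive in ~75% of replicates for the centre-distance rank, ~90% for
  mean centre distance), because a larger shoal has a core.
  The acceptance suite states the n = 5 expectation and is left failing
  for the centre-distance clause, deliberately: it documents a real
  limitation of the minimal model rather than a bug, and
  `analysis/02_individual_positioning.R` shows the group-size contrast.

## Problem sizes and numerical choices

The test and acceptance runs use 100 free-schooling replicates of 2000
steps, a 5 x 5 foraging grid (speed 0.4–2.0, $\omega$ 0.01–0.1) with 3
replicates of 10,000 steps per cell, 40 gamma-speed replicates, 100
planted-lag fixtures of 2400 frames with noise up to 20% of signal
s.d., and 120 white-noise null dyads of 3000 frames — sizes chosen so
the full analysis reruns comfortably on a laptop while leaving the sign
tests decisively powered.  Other numerics: unit direction vectors are
renormalized analytically at every step (turning is done in angle
space, so norms cannot drift); coincident agent positions trigger
maximal repulsion along a random direction and are counted; RNG
consumption order is fixed (agents in index order) so seeded runs are
bit-reproducible; Savitzky–Golay endpoints use the filter's one-sided
polynomial fits rather than truncation.
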