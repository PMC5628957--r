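# shoaldyn

Simulation and trajectory analysis of small fish shoals whose members
differ consistently in behaviour.  The package is built around a question
from collective animal behaviour: when individuals of a group differ
consistently in how fast they like to swim and how strongly they bias
their motion toward a goal, what does that do to the group — who ends up
in front, who leads, how cohesive and aligned is the shoal, and how well
does it find and deplete food?

Two halves, sharing one set of data structures:

* **A zonal self-propelled-particle model** (`sim_config()`,
  `run_experiment()`): agents with constant per-individual intrinsic speed
  (Gaussian or right-skewed Gamma draws) and goal-orientedness ω interact
  through repulsion / orientation / attraction zones with a 270° field of
  perception, wrapped-Gaussian heading noise and a capped turning rate, in
  a periodic free-schooling arena or a circular foraging arena with three
  depletable food patches.
* **A trajectory-analysis pipeline** that runs identically on simulator
  output and on empirical tracking tables (CSV of `frame,id,x_mm,y_mm` at
  24 fps, body length 40.6 mm by default): Savitzky–Golay smoothing and
  finite-difference kinematics (`kinematics()`), group geometry and order
  parameters — nearest-neighbour distance, centre distance, group-frame
  transform and front occupancy, cohesion (mean inter-individual
  distance), polarization (`group_metrics()`), frame-wise schooling
  classification with a 125-combination threshold robustness scan
  (`schooling_table()`, `robustness_grid()`), delay-correlation leadership
  networks (`dyad_delays()`, `leadership_network()`), and foraging
  analytics (`patch_discovery()`, `depletion_latencies()`,
  `cover_metrics()`, `behavior_scores()`).

The core order parameters are the standard ones: polarization
ρ = (1/n)‖Σᵢ(sin ψᵢ, cos ψᵢ)‖ ∈ [0, 1]; cohesion as the mean pairwise
distance IID; headings ψ = atan2(u, w) measured clockwise from +y. A
frame counts as *schooling* when IID ≤ 160 mm, centroid speed ≥ 0.5 BL/s,
ρ ≥ 0.6, and the group has no outlier or split (proximity-graph rule at
4 BL).  Leadership delays come from dyadic delayed correlations of speed
(Pearson) or heading (mean cosine) over lags up to ±72 frames (3 s at
24 fps), restricted to frames where the pair is closer than 4 BL and both
fish move faster than 1 BL/s; positive delay means the first fish leads.

## Worked example

```r
library(shoaldyn)

sim <- run_experiment(sim_config(), seed = 42)  # 5 agents, 2000 steps
gm  <- group_metrics(sim$gt)

mean(gm$per_frame$iid)                  # 9.72  (cohesive: ~10 BL spread)
mean(gm$per_frame$rho, na.rm = TRUE)    # 0.923 (highly aligned)

rbind(speed = sim$agents$speed, front = front_fraction(gm))
#>           a1     a2    a3     a4    a5
#> speed  1.155  0.881 1.015  0.891 1.161
#> front  0.928  0.035 0.525  0.025 0.903

cor(sim$agents$speed, front_fraction(gm), method = "spearman")
#> 0.8
```

The group stays cohesive (mean inter-individual distance ≈ 10 length
units, i.e. ~10 body lengths) and highly polarized (ρ ≈ 0.92), and the
two intrinsically fastest agents spend >90% of frames in front of the
group centroid while the two slowest almost never do — the sorting by
speed that makes faster individuals the de-facto leaders.  Across 100
seeds this speed→front correlation is positive in ~98% of replicates.

The numbered scripts under `analysis/` run the full study-style
workflow (replicated schooling simulations, positioning assortment,
group dynamics and the threshold robustness scan, leadership networks,
the foraging grid) and write their tables under `results/`.

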