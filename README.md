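# tempnets

Metrics for temporal contact networks recorded by proximity sensors, aimed
at epidemiological questions: how predictable are a network's contacts from
one time step to the next, how much do repeated contacts inflate naive
contact-tracing workload estimates, and can persistently highly connected
individuals ("superspreaders") be told apart from occasional drivers of
superspreading events?

## What it computes

Raw data are timestamped pairwise records (`t i j` edge lists at a fixed
recording resolution). `tempnets` aggregates them into contact episodes and
per-time-step snapshot graphs, then computes:

* **Retention index.** A retained contact is a pair in contact in two
  consecutive steps. With `k_t` an individual's degree in step `t` and `N`
  the population size, the observed mean retained contacts `r_temp` is
  rescaled between two null models,

  ```
  r = (r_temp - r_dyna) / (r_stat - r_dyna)
  ```

  where `r_stat = mean(k_t)` (static network: all contacts persist) and
  `r_dyna = E[min(k_t, k_{t+1}) k_{t+1}] / (N - 1)` (fully dynamic network:
  degrees drawn independently each step, each of the `min(k_t, k_{t+1})`
  earlier contacts kept with probability `k_{t+1}/(N-1)`). `r -> 1` means a
  static, predictable structure; `r -> 0` a fully dynamic one. Step pairs
  are summarised by the median and IQR, with the contact-type composition
  of retained pairs alongside.

* **Repeated-contact accounting.** Per study day: distinct contact pairs,
  cumulative distinct pairs, and the running sum of daily counts. Their gap
  is the overcount a planner incurs by assuming days are independent,
  reported relative to the population and to the true unique contacts, plus
  the distribution of encounter-days per pair.

* **Top-contributor persistence.** Per step, the smallest node set covering
  80% of contacts (or contact duration); over `S` steps, `rho_s` is the
  population fraction in that group for at most `s` steps. Individuals in
  the group for at least half the steps are potential superspreaders; those
  below a quarter are, if anything, drivers of superspreading events. The
  fully dynamic reference curve is `p80^s`.

Synthetic generators (static, degree-preserving fully dynamic, per-edge
partial retention with probability `q`, and multi-day records with per-pair
repeat probability `rho`) provide ground truth for every metric, including
calibration of negative-binomial overdispersion to a target top-group
fraction `p80`.

## Worked example

```r
library(tempnets)

series <- generate_partial_retention(N = 300, T_steps = 30, q = 0.6,
                                     degree_law = deg_poisson(5), seed = 42)
summarize_retention(series)
#> <retention_summary> 29 step pairs (29 defined)
#>   retention index: median 0.593 (IQR 0.585-0.604)

traj <- top_group_trajectory(series)
traj
#> <top_trajectory> 300 nodes over S = 30 steps (weight: contacts, top 80%)
#>   mean per-step top-group fraction p80 = 0.637
classes <- classify_contributors(traj)
vapply(classes, length, integer(1)) / length(traj$counts)
#> superspreaders    sse_drivers        neither
#>      0.6366667      0.3633333      0.0000000
```

The recovered median retention index (0.593) sits close to the generating
per-edge retention probability `q = 0.6` — the index reads off where the
network lies on the static–dynamic continuum. Because this generator keeps
per-node degrees fixed, top-group membership is highly persistent: about
64% of the population is in the top-80% group for at least half the steps.

Real data enter through `read_tij()` / `read_node_attributes()`, with
`network_presets()` carrying per-setting defaults (cruise, community, high
school, hospital, workplace, and fixed 15-min/1-h sensitivity settings). A
command-line wrapper is installed as `exec/tempnets` with subcommands
`simulate`, `snapshots`, `retention`, `repeats`, `topgroups` and `run`.

## Acceptance script

`scripts/acceptance.R` regenerates the reference-network quantities from
scratch with the installed package — the homogeneous static 80%/20%
always/never-identified split (N = 1000, 25 steps), the static-series
median retention index (N = 200, 20 steps), and the fully dynamic median
retention index pooled over 10 degree-preserving rewired series (N = 500,
50 steps) — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
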