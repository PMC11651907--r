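---
title: "Quantifying contact retention, repeated contacts and top-contributor persistence in temporal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contact retention, repeated contacts and top-contributor persistence in temporal networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempnets)
```

## The problem

Directly transmitted infections spread over social contact networks that
change in time. Epidemic models usually replace the measured temporal
network with one of two tractable extremes: a *static* network, in which the
same contacts persist forever, or a *fully dynamic* one, in which every
individual redraws their contacts at random each time step while keeping
their number of contacts. Where a real network sits between these extremes
determines how predictable transmission routes are, how many unique contacts
a tracing programme must handle, and whether highly connected individuals
("superspreaders") can be identified in advance.

`tempnets` computes three families of metrics on proximity-sensor contact
data (cruises, community, high schools, a hospital, workplaces — any data in
`t i j` edge-list form), together with synthetic generators that realise the
two extremes and everything in between, so that each metric can be validated
without access to the original sensor studies.

## From raw records to snapshots

Sensors record a contact every `resolution` seconds (15 s, 20 s or 300 s in
the source studies). A **contact episode** is a maximal run of consecutive
records for one pair; its length is the contact duration. Two per-network
statistics drive the analysis scale:

* the **median contact duration**, used as the validity threshold: a pair is
  in contact within a time step only if it accumulates at least this much
  recorded time in the step's window;
* the **median delay** between successive episodes of the same pair, used as
  the step length: shorter steps would make consecutive-step repetition
  artificially rare.

`build_snapshots()` tiles the study span with half-open windows of the step
length, anchored at the first record. Both parameters are configurable and
`network_presets()` stores the per-setting defaults (e.g. cruise 900 s/900 s,
community 300 s/600 s, hospital 20 s/140 s), plus the standardized
`fixed15min`/`fixed1h` sensitivity settings. Two readings of "lasts for at
least the median duration" are possible; the default uses *cumulative*
in-window time (the more inclusive reading), and `require_continuous = TRUE`
demands a single unbroken run instead. For the face-to-face settings the
presets use the tabulated 20 s median duration as the threshold; the
two-interval (40 s) proxy for continuous interaction described for those
sensors is obtained by passing `duration_threshold = 40` explicitly.

The population is fixed at all individuals ever observed; individuals
without contacts in a step have degree zero and still enter every
per-capita average.

## The retention index

A **retained contact** is a pair in contact in two consecutive steps. With
`k_t` the degree of an individual in step `t` and `N` the population size,
the number retained into step `t+1` is at most `min(k_t, k_{t+1})`. Two null
models bracket the observed mean retained contacts `r_temp`:

* **static null**: every contact persists, so retained contacts are
  distributed as the step-`t` degrees and `r_stat = mean(k_t)`;
* **fully dynamic null**: degrees at the two steps are independent draws
  from their empirical marginal distributions and each of the
  `min(k_t, k_{t+1})` earlier contacts persists independently with
  probability `k_{t+1}/(N-1)`, giving
  `r_dyna = E[min(k_t, k_{t+1}) k_{t+1}]/(N-1)`.

The **retention index**

```
r = (r_temp - r_dyna) / (r_stat - r_dyna)
```

locates the observed network on a 0–1 scale between the dynamic and static
extremes. It is reported unclamped (sampling noise can push individual step
pairs slightly outside `[0, 1]`; clamping would bias the median), and a step
pair is flagged undefined when the two null means coincide — an empty or
complete earlier snapshot — and excluded from the median/IQR summary, which
uses linear-interpolation (type 7) quantiles.

Numerical notes, in the package's own words:

* The binomial null with `p = 1` and degrees coupled across steps collapses
  exactly to the degree distribution — `null_retained_distribution(...,
  model = "static")` — and this identity is asserted exactly in the tests.
* The `min()` truncation makes the dynamic null an *approximation* to a
  graph-level degree-preserving rewiring. Under a rewiring that reassigns
  the later snapshot's degree multiset uniformly across nodes, the expected
  retained contacts are `mean(k_t) mean(k_{t+1})/(N-1)` exactly (every pair
  is equally likely to be an edge), which equals the analytic null whenever
  the earlier snapshot is a matching (all degrees ≤ 1). The Monte-Carlo
  oracle test therefore runs in that regime, where the identity is exact;
  for general snapshots the gap is of order the probability of degrees ≥ 2
  and is negligible relative to `r_stat - r_dyna` for the sparse networks
  this package targets (which is why the fully dynamic generator still
  recovers an index within ±0.05 of 0).
* An alternative `joint = TRUE` reading keeps each node's observed degree
  pair `(k_t, k_{t+1})` together instead of assuming marginal independence;
  both are exposed because the rewiring construction preserves per-node
  degrees while the null's algebra assumes independence.

## Repeated contacts across days

If day-to-day contacts were independent, summing each day's unique contacts
would estimate the tracing workload; in reality pairs repeat. For each day
`d`, `unique_contact_ledger()` reports the distinct pairs seen that day, the
cumulative distinct pairs since day 1, and the running sum of daily counts;
`overcount_metrics()` turns the difference into an absolute overcount and
two relative versions — per population member and per true unique contact.
Both are emitted because both normalisations are in common use and they
answer different planning questions; neither is silently preferred.
`encounter_days()` gives the distribution of the number of distinct days on
which each pair meets. Days are multiples of `day_length` (default 86 400 s)
from study start — sensor studies start mid-day, so calendar days are not
assumed.

The two-day worked example shipped in `inst/extdata/twoday_toy.tij` (day 1:
A–B, C–D, E–F; day 2: A–B, G–H, I–J) yields 5 cumulative unique pairs
against a summed count of 6: an overcount of 1, i.e. 10% of the 10-person
population or 20% of the true unique contacts.

A related quantity sometimes quoted — "the proportion of contacts that
occurred over one day" — admits two readings: the fraction of *pairs*
meeting on exactly one day (`distribution$proportion[1]` from
`encounter_days()`), or the fraction of contact *records* falling within a
single day. Both are computable from the returned objects; the package
deliberately does not pick one.

## Superspreaders versus superspreading events

In each step the **top group** is the smallest set of individuals whose
contacts (or contact duration) cover at least 80% of the step's total. Ties
are broken deterministically (weight descending, then node id) so results
are exactly reproducible; `random_ties = TRUE` exists for sensitivity
analysis. Over `S` steps, `rho_s` is the fraction of the population in the
top group for *at most* `s` steps; `rho_S = 1` by construction. Individuals
in the top group for at least half the steps are labelled potential
**superspreaders**; those identified for less than a quarter of the steps
are, if anything, drivers of **superspreading events**. The `>=` / `<`
conventions and the unrounded fractional thresholds follow the "at least
half" / "less than a quarter" definitions; both cut-offs are configurable.
Steps without contacts contribute no membership but count toward `S` by
default (`skip_empty_steps` reverses this).

Two reference curves contextualise observed persistence: a static network
keeps the same top group every step (a homogeneous one identifies 80% of the
population in all steps and 20% never), and a fully dynamic network with
per-step top-group fraction `p80` identifies a fraction approximately
`p80^s` of the population for at least `s` steps (`dynamic_reference_curve()`).
The homogeneous reference uses `p80 = 0.8`; the overdispersed reference uses
`p80 = 0.5`. Two further printed reference values for dynamic networks at 25
and 10 steps are not derivable from either the binomial null or the `p80^s`
approximation and are deliberately not reproduced.

One subtlety the tests make explicit: with the contacts weighting,
top-group membership is a deterministic function of per-node degrees. A
degree-preserving dynamic network (degrees fixed, edges rewired) therefore
keeps the *same* top group every step even though its retention index is
near 0 — edge identity and hub identity are different notions of
predictability. The dynamic membership reference is instead realised by a
homogeneous network with random tie-breaking, whose membership is freshly
drawn each step and whose always-identified fraction decays to `p80^S`.
Note also that for any membership-resampling process the fraction
identified for *at least* `s` steps exceeds the static `p80` at small `s`
(nearly everyone is identified at least once); the dynamic curve drops
below the static one only as `s` grows.

## Synthetic generators: the stated world

The generators exist so every metric has a ground truth:

* `generate_static(N, T)` — one configuration-model graph repeated;
* `generate_fully_dynamic(N, T)` — per-node target degrees fixed once, each
  step an independent simple-graph realization (degree-preserving
  rewiring);
* `generate_partial_retention(N, T, q)` — each edge persists with
  probability `q` per step, freed stubs re-paired at random avoiding
  self-loops, multi-edges and kept edges; `q = 1` is static, `q = 0`
  redraws every edge;
* `generate_multiday()` — raw `t i j` records with day structure and
  per-pair daily repeat probability `rho`, for the ledger metrics.

Default degree law is Poisson with mean 5, matching the observation that
most individuals have a handful of contacts per step; reference experiments
use `N = 500–1000` and `T = 20–50`, the scale of the source studies'
populations. Overdispersion is parameterised by negative-binomial dispersion
and *calibrated* (`calibrate_p80()`) until the realised top-group fraction
hits a target `p80` within 0.02, because the concentration level — not a
particular distribution — is what the reference networks specify. Degree
sequences are made feasible by decrementing a random positive degree on an
odd stub sum and the largest degrees until graphical; single-step graphs are
sampled with igraph's configuration-model heuristics. The re-pairing of
freed stubs in the partial-retention generator uses bounded iterative
repair (clashing pairs are broken together with randomly chosen good pairs
and reshuffled); irreparable leftovers — vanishingly rare at the default
densities — are dropped with a warning.

What the generators deliberately do **not** emulate: diurnal activity
rhythms, overnight recording gaps, household/venue structure, device
calibration differences, or open populations with missing contacts. A green
test on synthetic data therefore establishes the correctness of the
metrics' computation and their limiting behaviour, not the empirical claims
about any particular real-world setting.

Every generator is seed-reproducible: same configuration and seed give
bit-identical series.

## Worked example

```{r example}
series <- generate_partial_retention(N = 300, T_steps = 30, q = 0.6,
                                     degree_law = deg_poisson(5), seed = 42)
summarize_retention(series)

traj <- top_group_trajectory(series)
classes <- classify_contributors(traj)
vapply(classes, length, integer(1)) / length(traj$counts)
```

The recovered median retention index sits near the generating `q = 0.6`, and
with substantial retention a sizeable fraction of the population is
persistently in the top group.

## Known limitations

* The dynamic null is the binomial approximation described above, not an
  exact rewiring expectation; both disagree at order `E[k]/N` for dense or
  heavily overdispersed snapshots.
* Directed analyses treat a node's degree as the number of contacts it is
  involved in; simultaneous `i→j` and `j→i` records count as two directed
  contacts (the undirected switch collapses them), and the `N - 1` degree
  bound is interpreted per direction.
* No higher-order structure (clustering, motifs) enters the retention
  metric, and no transmission model is included.
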