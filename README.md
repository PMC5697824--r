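# schoolturn

Inferring who follows whom in a school of fish, from trajectories alone.

Small groups of rummy-nose tetras swimming in a ring-shaped tank circulate
along the corridor and, every so often, perform a **collective U-turn**: one
fish reverses its direction of travel and the others follow within fractions
of a second. `schoolturn` implements a time-resolved, data-driven procedure
that identifies, at every video frame, which neighbor(s) a focal fish is
copying and with what time delay — an **influence network** over the group —
together with the null model and parameter-sensitivity machinery needed to
trust it.

## The method

Headings are defined from the velocity, `v_i = ||v_i|| (cos φ_i, sin φ_i)`.
For a focal fish `i` and neighbor `j`, the **directional correlation** at
delay `τ` is the dot product of unit headings

    H_ij(t, τ) = e_i(t) · e_j(t − τ)

and its average over a sliding window of `2w + 1` frames is
`C_ij(t, τ, w)`. The per-frame delay `τ*_k` is extracted recursively: at
frame `k` it is the smallest delay maximizing `C_ij(t_k, τ, w)` over the
search range `[0, τ*_{k−1} + 1]` (a fish never reaches further back in its
neighbor's past than one extra frame per elapsed frame; the recursion starts
from a bound of 50 frames). Neighbor `j` is an **influential neighbor** of
`i` at `t` when `C_ij(t, τ*, w) > C_min` and `τ* > τ_R`, a reaction-time
floor; among passing neighbors, all scoring within `ε` percent of the best
also count. Defaults: `w = 2` frames, `C_min = 0.95`, `ε = 3`,
`τ_R = 0.04 s` at 50 Hz sampling.

Around this core the package provides:

- **Trajectory handling** — delimited-text I/O, gap interpolation (runs of
  up to 50 missing frames), Cartesian/polar conversion
  (`read_trajectories()`, `interpolate_gaps()`, `to_polar()`).
- **Kinematics** — velocity, heading, wall-incidence angle `θ_w = φ − ψ`,
  pairwise geometry, group polarization `P(t) = ||Σ e_i|| / N`, and
  burst/coast segmentation (`compute_kinematics()`, `pair_geometry()`,
  `polarization_series()`, `detect_bursts()`).
- **U-turn detection** — individual turn instants from persistent sign
  changes of `sin θ_w`, start/end bounds from moving-average thresholds,
  collective events as `t_s = min_i t_s,i`, `t_e = max_i t_e,i`, normalized
  event time, and position/distance/turning ranks (`detect_uturns()`).
- **Influence inference** — the delay recursion and identification rules
  above, neighbor counts `N_if`, their relative variation `η`, and
  chain-of-influence removal (`extract_delays()`, `identify_influential()`,
  `remove_influence_chains()`).
- **Aggregation** — rank/count histograms, normalized-time courses of
  speed, polarization and `N_if`, focal-frame spatial density and
  relative-velocity maps, and delay-versus-geometry maps
  (`rank_histograms()`, `time_course()`, `spatial_map()`, `delay_map()`).
- **Null model** — artificial collective U-turns assembled from
  independently sampled, rotated, time-shifted and mirrored individual
  U-turn tracks, pushed through the identical pipeline to expose
  correlations that arise without interaction
  (`uturn_track_pool()`, `generate_null_ensemble()`).
- **Sensitivity** — the 40-combination `(w, ε, C_min)` sweep compared by
  cosine similarity of 19-dimensional summary vectors, plus data-retention
  curves versus `C_min` (`similarity_matrix()`, `retention_curve()`).
- **Synthetic schools** — a seeded generator that implants a known
  influence graph (who copies whom, at which lag) into ring-constrained
  trajectories, providing labeled ground truth for every stage
  (`simulate_school()`, `make_fixture_suite()`).

## Worked example

```r
library(schoolturn)

# a 5-fish school: fish 1 initiates, 2 copies 1 (0.2 s), 3 copies 2, ...
cfg <- sim_config(
  n_fish = 5, duration = 12, uturn_times = 6,
  influence_graph = list(
    `2` = list(influencer = "1", delay = 10),
    `3` = list(influencer = "2", delay = 12),
    `4` = list(influencer = "3", delay = 14),
    `5` = list(influencer = "4", delay = 16)),
  kappa = 100, seed = 3)
sim <- simulate_school(cfg)

an <- analyze_uturn(sim$trajectories)
glance(an)
#> # A tibble: 1 × 5
#>   n_events n_records mean_tau mean_n_if modal_n_if
#>      <int>     <int>    <dbl>     <dbl>      <int>
#> 1        1      2571    0.255      1.78          2

glance(an$events)
#> # A tibble: 1 × 7
#>   event_id n_fish   t_s   t_e duration direction_before direction_after
#>      <int>  <int> <dbl> <dbl>    <dbl> <chr>            <chr>
#> 1        1      5   5.8  7.72     1.92 anticlockwise    clockwise
```

One collective U-turn is detected: all five fish reverse from anticlockwise
to clockwise between 5.8 s and 7.72 s (the initiator was scripted at 6 s
and the followers lag by their cumulative delays; the collective bounds
are the earliest individual start and the latest individual end). Each
fish typically has one or two influential neighbors at a time — in a chain,
the direct influencer plus a chain shortcut — and the mean extracted delay
of 0.26 s sits among the implanted per-link lags (0.20–0.32 s). The
time-resolved influence edge list is in `an$records`
(`time, focal, neighbor, tau, C`), and
`extract_delays(an$kin, "2", "1", analysis_config())` shows fish 2's delay
to fish 1 locked at the implanted 10 frames over the bulk of the record.

Plots: `autoplot(time_course(an))`, `plot_rank_histograms(rank_histograms(an))`,
`autoplot(spatial_map(an$records, an$pairs))`.

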