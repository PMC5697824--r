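---
title: "Inferring influential neighbors from time-delayed directional correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring influential neighbors from time-delayed directional correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolturn)
```

## The problem

Schooling fish share directional information continuously, but it is not
observable *which* neighbor an individual is attending to at a given
moment. In a ring-shaped tank the group's behavioral repertoire collapses
to two directions of travel — clockwise or anticlockwise — punctuated by
collective U-turns in which one fish reverses and the rest follow within
fractions of a second. Those reversals are the analysis window of choice:
a large, unambiguous heading change must propagate through the group, so
directional correlations during U-turns reflect direct behavioral
coupling much more than the incidental alignment produced by the channel
geometry.

`schoolturn` operationalizes "fish `j` influences fish `i`" as: `i`'s
current heading matches `j`'s heading a little while ago, persistently
and at a plausible reaction delay. Everything else in the package exists
to make that operationalization precise, testable, and falsifiable.

## Model and procedure

**Headings and incidence.** With positions sampled at `1/dt` (default
50 Hz), velocities are one-frame central differences and the heading is
`phi = atan2(vy, vx)`, held at its last defined value whenever speed
drops below `speed_floor` (default 1 mm/s) to keep `atan2` noise out of
the analysis. With `psi` the angular position about the tank center, the
wall-incidence angle is `theta_w = wrap(phi - psi)`: about `+90°` when
cruising anticlockwise, `-90°` clockwise; the sign of `sin(theta_w)`
encodes the circulation direction.

**U-turn segmentation.** A candidate individual turn instant `t_m` is a
sign change of `sin(theta_w)` whose mean over `persistence = 25` frames
on each side exceeds `min_abs_sin = 0.5` in absolute value with opposite
signs — so a fish that merely wobbles across zero for a few frames does
not register. The turn's start threshold is the maximum of the absolute
5-frame moving average of `sin(theta_w)` over the 50 frames before `t_m`
(end: after `t_m`); stepping away from `t_m`, the first frames where
`|sin(theta_w)|` exceeds those thresholds give `t_s,i` and `t_e,i`. The
sine rather than the raw angle is deliberate: it saturates at 1 whenever
the fish is wall-parallel, so the thresholds — maxima of a bounded
statistic — barely move when the span they are computed over doubles,
whereas the unbounded excursions of the raw angle make its maxima grow
with the span and the bounds jump between heading-kick peaks. Individual
turns of different fish sharing a direction change within `assoc_window =
3 s` form one collective event with `t_s = min_i t_s,i` and
`t_e = max_i t_e,i`. Event time is normalized as
`t_bar = (t - t_s) / (t_e - t_s)` and analyses run over
`t_bar` in `[-1, 2]`.

**Delay extraction.** The directional correlation
`H_ij(t, tau) = e_i(t) . e_j(t - tau)` is averaged over a centered window
of `2w + 1` frames to give `C_ij(t, tau, w)`. Delays are tracked
recursively: the delay at frame `k` is the smallest `tau` in
`[0, tau*_{k-1} + 1]` maximizing `C_ij`, initialized from a bound of
`tau0 = 50` frames. The growth bound encodes the assumption that once `i`
has been found copying `j`'s past at lag `tau`, it will not later copy
anything *older* than that by more than one frame per elapsed frame.

Two numerical choices matter here and are deliberate:

- *Activation.* The recursion begins at the first frame whose history
  covers the whole initial range `[0, tau0 + 1]`. Starting earlier, with
  only small delays available, would pin this greedy tracker at whatever
  small lag happens to exist; the one-frame-per-frame growth bound can
  then never carry it across a dip in the correlation profile to the true
  peak. Frames before activation are reported as missing, never
  zero-filled — as are all cells of the correlation field whose window
  would reach before the start of the record.
- *Ties.* Exact ties in the argmax resolve to the smallest delay.

**Identification.** Neighbor `j` is influential for `i` at frame `k`
when `C_ij(t_k, tau*_k, w) > c_min` **and** `tau*_k dt > tau_r`. The
reaction-time floor (default 0.04 s) discards the near-zero delays that
dominate whenever the group is already polarized — alignment at
effectively zero lag carries no information about who is copying whom.
Among gate-passing neighbors, all scoring within `eps` percent of the
best score also qualify, so genuinely tied neighbors count as
simultaneous influencers. The literature this method descends from names
`eps` but never defines its rule; the percent-of-maximum reading matches
both the parameter's magnitude (3–5) and its described role, and it is
isolated behind a single predicate so an alternative is a one-line swap.
Defaults `w = 2`, `c_min = 0.95`, `eps = 3` correspond to the
sensitivity analysis below.

**Counting and chains.** `N_if(i, t)` counts distinct influential
neighbors; the rank and count histograms report proportions of the time
spent *inside* the collective U-turn (`t_bar` in `[0, 1]`), with the
full analysis window available via `span = "window"`. The relative
variation of the count is
`eta(t) = |N_if(t + dt) - N_if(t)| / N_if(t)`, undefined (and excluded
from averages) where `N_if = 0`. Because correlation chains can fake
direct influence, `remove_influence_chains()` drops the edge `(F1, F2)`
whenever `F1` is simultaneously influenced by `F2` and `F3` while `F2`
is influenced by `F3`; the operation never adds records and is
idempotent.

## The null model

Correlation is not causation, so the pipeline ships its own control:
artificial collective U-turns assembled from genuinely independent
individual turns. From every detected event, each fish's polar track
(event window extended by one duration or 3 s, whichever is larger) joins
a pool with its turn instant `T_i`. An artificial U-turn samples five
tracks from five distinct source events, rotates each by
`-psi(T_i) + pi/2 + xi_i` with `xi_i` uniform in `[-pi/12, pi/12]` (all
turns relocate to the top of the tank), shifts each clock by
`-T_i + zeta_i` with `zeta_i` uniform in `[-1, 1] s` (snapped to the
frame grid so the group shares one clock), and mirrors tracks across the
vertical axis (`psi -> pi - psi`, an involution that flips circulation
while keeping the relocated turn region in place) until all five
circulate like a randomly chosen reference fish. The identical pipeline
then runs on the result. The pool margin of at least 3 s is this
package's choice: it guarantees that time-shifted tracks retain a usable
common span and that artificial events are long enough for the delay
recursion to activate.

## The synthetic-data generator

No trajectory data are distributed with the package; the generator is the
ground-truth instrument, and it implants exactly the structure the
inference assumes — no more. Root fish steer tangentially along the
corridor (with a near-critically damped radial pull toward a cruise
radius just inside the midline) and reverse at scripted times by sweeping
their heading through the wall-facing direction over `turn_duration =
0.6 s` (individual turns of real fish last 0.4–1 s) with a scripted speed
dip. Every follower's heading is its influencer's heading a fixed number
of frames earlier, plus von Mises copying noise; its speed is the
delayed speed; and its path starts where the influencer started, so a
noiseless follower retraces the influencer's path exactly and the
implanted delay is exact by construction. A weak positional pull toward
the influencer's delayed position (zero when exactly on the path) stops
copying noise from accumulating into a radial random walk.

The root heading carries a deliberately irregular "wiggle":

- discrete heading kicks at quasi-regular intervals (mean 0.32 s, gaps
  jittered 0.8–1.2x) whose levels alternate sign with strongly jittered
  magnitude (mean 0.55 rad, sd half of that) — the left/right zigzag of
  burst-and-coast swimming; the magnitude jitter matters because two
  *independent* fish whose zigzag phases happen to agree would otherwise
  hold near-identical heading offsets and register as spuriously
  correlated;
- a fast fine dither (sd 0.25 rad, ~1.5-frame correlation, tails clamped
  at 1.5 sd) mimicking the yaw of body undulation. Followers copy the
  dither along with the rest of the heading, so it costs true edges
  nothing while setting a mismatch floor between fish that do not
  interact: two independent dithers rarely cancel, and their combined
  spread alone holds the windowed correlation of non-interacting pairs
  near the identification threshold.

This is not decoration. The delay is identifiable only insofar as the
heading series is informative: a steady heading leaves every delay
equally good, and a periodic one aliases the true lag with its
harmonics. The alternating-sign kick process has a monotonically
decaying autocorrelation (no spurious local maxima for the greedy
tracker to get caught on) and the dither sharpens the correlation peak
at the true lag at every frame. Kick activity is damped fourfold during
the scripted reversal sweep — the maneuver itself is the signal there —
which also keeps the incidence angle's zero crossing unique and clean
for the detector. Each root fish draws its own sweep duration
(0.75–1.25x of the 0.6 s default) and a fish-specific monotone S-curve
sweep profile: independent turners with *identical* scripted sweeps
would correlate strongly whenever their turns overlap, which is exactly
the artifact the fixtures must not manufacture. Followers can additionally carry an idiosyncratic fast
heading component (`own_wiggle`): real fish are not pure copyists, and
without individuality two followers of a common influencer are almost as
correlated with each other as with their influencer, making hub
recovery impossible in principle.

The labeled fixture suite (`make_fixture_suite()`) contains a
leader–follower pair at lag 20 frames (noiseless and with `kappa = 100`
noise; the pair recordings run 30 s, since delay-recovery summaries are
per-frame statistics and a long stationary record dilutes the
occasional drop-and-climb episode of the constrained tracker), a 5-fish
chain with per-link lags 10–16 frames, a 5-fish star in
which all followers copy the hub at the same lag (so any
follower–follower alignment sits at delay zero, below the reaction-time
floor, and only the direct edges survive the gates), and five
independent turners. What these fixtures *do* show when the pipeline
passes: the delay recursion, gating and counting recover implanted
structure under realistic heading variability and noise. What they do
*not* show: performance on real video (tracking errors, identity swaps,
occlusions), hydrodynamic or visual interaction mechanisms, 3D effects,
or group sizes beyond a handful of fish.

## Parameter sensitivity

The sweep runs all 40 combinations of `w` in 0–4, `eps` in {3, 5} and
`c_min` in {0.995, 0.99, 0.95, 0.5}; each yields four histograms
(counts, distance rank, position rank, turning rank of influential
neighbors) concatenated into a 19-dimensional proportion vector, and
combinations are compared by cosine similarity. Delay tracks depend only
on `w`, so they are computed once per `w` and reused — a pure
optimization with asserted output equivalence. Data retention versus
`c_min` counts (focal, frame) points with at least one gate-passing
neighbor; it is monotone nonincreasing by construction, and the default
`c_min = 0.95` sits at the last value before retention falls steeply on
the synthetic datasets shipped with the tests.

## Numerical conventions and degenerate inputs

Millimetres and seconds throughout; angles in radians wrapped to
`(-pi, pi]`, anticlockwise positive; frames index from 0 and timestamps
are authoritative. Undefined quantities (headings below the speed floor
with no history, polarization with a missing heading, viewing angles at
coincident positions, `eta` at zero counts, masked correlation cells)
propagate as explicit `NA`, never silent zeros. Boundary gaps in
tracking are never extrapolated — only interior runs of at most
`max_gap = 50` frames are interpolated, the rest are reported. Rank ties
break by ascending fish id. Moving averages shrink their window at
series edges rather than padding.

## Problem sizes used in validation

The shipped checks run entirely on generated data: 12-second recordings
(600 frames) at 50 Hz, groups of 2 or 5 fish; ensemble comparisons use
150–200 structured events against equally many artificial events, and
the sensitivity sweep uses 20 recordings. These sizes give stable
ensemble averages (grid-point mean counts, histogram masses) while
keeping the full suite comfortably reproducible on a laptop.

## Known limitations

- The burst detector's operational rule (threshold on the smoothed
  acceleration, extended to the surrounding speed minimum/maximum) is
  this package's own; the burst-and-coast literature fits an explicit
  kinematic model instead.
- The `eps` rule is one defensible reading of an under-specified
  parameter (see above).
- Whether the segmentation thresholds should average `theta_w` or
  `sin(theta_w)` is ambiguous in the source literature; `theta_w` is
  used here.
- Near-zero delays are discarded by `tau_r` rather than modeled; in
  highly polarized stretches the method is simply silent about who leads.
- The null model decorrelates individual turns but keeps each track's
  internal kinematics; it does not address alternative nulls such as
  phase randomization.
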