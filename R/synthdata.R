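#' Configuration for the synthetic ring-school generator
#'
#' The generator implants exactly the statistical structure the influence
#' analysis assumes: fish travel the annular corridor; a designated
#' initiator reverses its circulation at scripted times with a smooth
#' heading ramp and a speed dip; every follower copies its influencer's
#' heading with a fixed, known lag (in frames) plus von Mises noise, and
#' the follower's path is the influencer's path shifted in time, so the
#' implanted delays are exact.
#'
#' An irregular heading "wiggle" rides on each root fish's tangential
#' heading: discrete heading kicks at quasi-regular intervals whose levels
#' alternate sign with jittered magnitude (the left/right zigzag of
#' burst-and-coast swimming), plus a fast fine dither mimicking the yaw of
#' body undulation. Together they make the heading series aperiodic and
#' informative at every time scale, which is what lets the delayed
#' correlation peak uniquely at the true lag: a perfectly steady heading
#' would leave the delay unidentifiable, and a strictly periodic one would
#' alias it.
#'
#' @param n_fish group size (>= 1).
#' @param dt frame interval (s); default 0.02 (50 Hz).
#' @param duration length of the returned record (s).
#' @param geometry a [ring_geometry()].
#' @param influence_graph named list `follower -> list(influencer, delay)`
#'   with delay in frames (>= 1); fish absent from the list are
#'   independent roots. Ids are `"1".."n_fish"`.
#' @param kappa von Mises concentration of the heading noise; `Inf`
#'   (default) means noiseless.
#' @param own_wiggle standard deviation (rad) of a fast idiosyncratic
#'   heading component added to each follower on top of the copied
#'   heading. Real fish are not pure copyists; without individuality,
#'   every two followers of a common influencer are almost as correlated
#'   with each other as with their influencer, and the direct edges
#'   cannot dominate. Default 0 (pure copying).
#' @param noise_interval frames between fresh copying-noise draws
#'   (default 1, i.e. independent per frame); larger values hold each
#'   deviate constant in between, for copying errors that persist over a
#'   reaction time.
#' @param cruise_speed cruising speed, mm/s.
#' @param dip_fraction fractional speed dip at mid U-turn (0..1).
#' @param turn_duration mean duration of the scripted heading ramp (s);
#'   each root fish draws its own within 0.75..1.25 of it, so independent
#'   turners do not share identical sweep shapes.
#' @param uturn_times times (s, on the output clock) at which each root
#'   fish starts its scripted reversal. Followers reverse automatically,
#'   later by their cumulative lag.
#' @param wiggle_amp mean magnitude of the heading-kick levels (rad).
#' @param wiggle_period mean interval between heading kicks (s); actual
#'   gaps are jittered uniformly within 0.8..1.2 of it.
#' @param burst_period period of an optional square-wave burst-and-coast
#'   speed envelope (s); 0 disables it.
#' @param burst_fraction fraction of each period spent bursting.
#' @param seed integer RNG seed; the output is fully determined by it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_fish = 5, dt = 0.02, duration = 12,
                       geometry = ring_geometry(),
                       influence_graph = list(),
                       kappa = Inf, cruise_speed = 130,
                       dip_fraction = 0.5, turn_duration = 0.6,
                       uturn_times = 6, wiggle_amp = 0.55,
                       wiggle_period = 0.32, own_wiggle = 0,
                       noise_interval = 1,
                       burst_period = 0, burst_fraction = 0.3, seed = 1L) {
  stopifnot(n_fish >= 1, dt > 0, duration > 0, cruise_speed > 0,
            dip_fraction >= 0, dip_fraction < 1, turn_duration > 0,
            all(uturn_times > 0), all(uturn_times < duration))
  for (f in names(influence_graph)) {
    if (influence_graph[[f]]$delay < 1) {
      stop("influence delays must be >= 1 frame", call. = FALSE)
    }
  }
  structure(list(n_fish = as.integer(n_fish), dt = dt, duration = duration,
                 geometry = geometry, influence_graph = influence_graph,
                 kappa = kappa, cruise_speed = cruise_speed,
                 dip_fraction = dip_fraction, turn_duration = turn_duration,
                 uturn_times = uturn_times, wiggle_amp = wiggle_amp,
                 wiggle_period = wiggle_period, own_wiggle = own_wiggle,
                 noise_interval = as.integer(noise_interval),
                 burst_period = burst_period,
                 burst_fraction = burst_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

# topological order of the influence graph; error on cycles
topo_order <- function(n_fish, graph) {
  ids <- as.character(seq_len(n_fish))
  parent <- setNames(rep(NA_character_, n_fish), ids)
  for (f in names(graph)) parent[f] <- as.character(graph[[f]]$influencer)
  order <- character(0)
  placed <- setNames(rep(FALSE, n_fish), ids)
  for (id in ids) {
    chain <- character(0)
    cur <- id
    while (!is.na(parent[cur]) && !placed[cur]) {
      if (cur %in% chain) stop("influence graph has a cycle", call. = FALSE)
      chain <- c(chain, cur)
      cur <- parent[cur]
    }
    for (c0 in rev(chain)) {
      if (!placed[c0]) { order <- c(order, c0); placed[c0] <- TRUE }
    }
    if (!placed[id]) { order <- c(order, id); placed[id] <- TRUE }
  }
  # roots first, then children in dependency order
  depth <- setNames(integer(n_fish), ids)
  for (id in ids) {
    d <- 0L; cur <- id
    while (!is.na(parent[cur])) { d <- d + 1L; cur <- parent[cur] }
    depth[id] <- d
  }
  ids[order(depth, as.integer(ids))]
}

#' Simulate a school of fish performing collective U-turns in a ring
#'
#' See [sim_config()] for the model. Root fish are steered tangentially
#' along the corridor midline with weak radial feedback; each follower's
#' heading is its influencer's heading `delay` frames earlier plus von
#' Mises noise, its speed the influencer's delayed speed, and its starting
#' position the influencer's position `delay` frames earlier, so in the
#' noiseless case the follower retraces the influencer's path exactly.
#' Positions are hard-clipped to the annulus as a safety margin (noise can
#' push a follower off the path).
#'
#' @param config a [sim_config()].
#' @return a list with
#'   \describe{
#'   \item{trajectories}{a `trajectory_set` (times from 0, frames from 0)}
#'   \item{truth}{ground truth: `influence` (tibble `follower, influencer,
#'     delay_frames, total_shift`), `uturn_schedule` (tibble `id,
#'     t_scheduled, t_m_true` with the realized mid-turn instant computed
#'     from the scripted headings), and `headings` (tibble `frame, time,
#'     id, phi, speed` of the scripted series)}
#'   }
#' @export
simulate_school <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$geometry
  dt <- config$dt
  r_mid <- (g$outer_radius + g$inner_radius) / 2
  band <- (g$outer_radius - g$inner_radius) / 2 - 10
  # cruise slightly inside the midline: the scripted reversal sweeps the
  # heading through the outward (wall-facing) direction, so the turn
  # excursion moves the fish toward the outer wall and needs headroom
  r_cruise <- r_mid - 10
  n_out <- floor(config$duration / dt) + 1L
  ids <- as.character(seq_len(config$n_fish))
  ord <- topo_order(config$n_fish, config$influence_graph)

  # cumulative shift of each fish from its root
  shift <- setNames(integer(config$n_fish), ids)
  for (f in ord) {
    link <- config$influence_graph[[f]]
    if (!is.null(link)) {
      shift[f] <- shift[as.character(link$influencer)] + as.integer(link$delay)
    }
  }
  S <- max(shift)
  K <- n_out + S # extended frame axis; output = frames (S+1)..K

  roots <- ids[!ids %in% names(config$influence_graph)]
  uturn_times <- rep_len(config$uturn_times, length(roots))
  turn_dur <- setNames(rep(config$turn_duration, config$n_fish), ids)

  phi <- matrix(NA_real_, K, config$n_fish, dimnames = list(NULL, ids))
  spd <- matrix(NA_real_, K, config$n_fish, dimnames = list(NULL, ids))
  px <- matrix(NA_real_, K, config$n_fish, dimnames = list(NULL, ids))
  py <- matrix(NA_real_, K, config$n_fish, dimnames = list(NULL, ids))

  t_ext <- (seq_len(K) - 1 - S) * dt # output clock on the extended axis

  speed_profile <- function(tt, turn_starts, dur) {
    v <- rep(config$cruise_speed, length(tt))
    for (t0 in turn_starts) {
      ramp <- (tt - t0) / dur
      inturn <- ramp >= 0 & ramp <= 1
      v[inturn] <- v[inturn] * (1 - config$dip_fraction * sin(pi * ramp[inturn]))
    }
    if (config$burst_period > 0) {
      phase <- (tt %% config$burst_period) / config$burst_period
      v <- v * ifelse(phase < config$burst_fraction, 1.5, 0.8)
    }
    v
  }

  for (f in ord) {
    link <- config$influence_graph[[f]]
    if (is.null(link)) {
      # root: tangential steering + scripted reversals + wiggle + noise
      iroot <- match(f, roots)
      turns <- uturn_times[iroot]
      # per-root sweep duration and profile shape: identical sweeps would
      # make independent turners look correlated during overlapping turns
      dur_f <- runif(1, 0.75, 1.25) * config$turn_duration
      turn_dur[f] <- dur_f
      shape_f <- runif(1, -1, 1)
      psi0 <- runif(1, -pi, pi)
      x <- r_cruise * cos(psi0); y <- r_cruise * sin(psi0)
      wig_series <- draw_wiggle(K, config$wiggle_amp,
                                config$wiggle_period, dt)
      # roots are deterministic given the seed draws: the von Mises noise
      # models copying errors, which only followers make
      noise <- numeric(K)
      v <- speed_profile(t_ext, turns, dur_f)
      rho_prev <- NA_real_
      for (k in seq_len(K)) {
        psi <- atan2(y - g$center[2], x - g$center[1])
        rho <- sqrt((x - g$center[1])^2 + (y - g$center[2])^2)
        drho <- if (is.na(rho_prev)) 0 else (rho - rho_prev) / dt
        rho_prev <- rho
        tt <- t_ext[k]
        ramp_idx <- which(tt >= turns & tt <= turns + dur_f)
        wig <- wig_series[k]
        if (length(ramp_idx)) {
          t0 <- turns[ramp_idx[1]]
          ramp <- (tt - t0) / dur_f
          # monotone S-curve distortion of the sweep (single crossing of
          # the wall-normal direction, but a fish-specific time profile)
          ramp <- ramp + 0.3 * sin(pi * ramp) * shape_f
          s_before <- if (sum(turns < t0) %% 2 == 0) 1 else -1
          # the reversal is a deliberate sweep through the wall-facing
          # direction (incidence angle dips through zero, as in the
          # operational definition of an individual U-turn); kick
          # activity is largely suspended while the maneuver is executed
          h <- psi + s_before * (pi / 2 - pi * ramp) + 0.25 * wig
        } else {
          s_cur <- if (sum(turns <= tt) %% 2 == 0) 1 else -1
          # near-critically damped pull toward the cruise radius: for
          # either circulation sense a positive s*delta rotates inward
          steer <- s_cur * (0.006 * (rho - r_cruise) + 0.0135 * drho)
          steer <- min(max(steer, -0.35), 0.35)
          h <- psi + s_cur * pi / 2 + wig + steer
        }
        h <- wrap_angle(h + noise[k])
        phi[k, f] <- h
        spd[k, f] <- v[k]
        px[k, f] <- x; py[k, f] <- y
        x <- x + v[k] * cos(h) * dt
        y <- y + v[k] * sin(h) * dt
        # hard clip to the corridor
        rho2 <- sqrt((x - g$center[1])^2 + (y - g$center[2])^2)
        if (rho2 > r_mid + band || rho2 < r_mid - band) {
          rho_c <- min(max(rho2, r_mid - band), r_mid + band)
          ang <- atan2(y - g$center[2], x - g$center[1])
          x <- g$center[1] + rho_c * cos(ang)
          y <- g$center[2] + rho_c * sin(ang)
        }
      }
    } else {
      gfish <- as.character(link$influencer)
      L <- as.integer(link$delay)
      noise <- draw_heading_noise(K, config$kappa, config$noise_interval)
      # idiosyncratic fast heading component (individuality): decorrelates
      # siblings that copy the same source from the direct edge
      own <- draw_dither(K, config$own_wiggle)
      src <- c(rep(1L, L), seq_len(K - L))
      phi[, f] <- wrap_angle(phi[src, gfish] + own + noise)
      spd[, f] <- spd[src, gfish]
      # hold position during the first L (discarded burn-in) frames, then
      # integrate from the influencer's start point: in the noiseless case
      # the follower exactly retraces the influencer's path L frames later.
      # A weak positional pull toward the influencer's delayed position
      # (cohesion) keeps noise-driven drift from accumulating; it vanishes
      # when the follower is exactly on the delayed path.
      x <- px[1, gfish]; y <- py[1, gfish]
      lambda <- 0.02
      for (k in seq_len(K)) {
        px[k, f] <- x; py[k, f] <- y
        if (k <= L) next
        x <- x + spd[k, f] * cos(phi[k, f]) * dt +
          lambda * (px[k - L, gfish] - x)
        y <- y + spd[k, f] * sin(phi[k, f]) * dt +
          lambda * (py[k - L, gfish] - y)
        rho2 <- sqrt((x - g$center[1])^2 + (y - g$center[2])^2)
        if (rho2 > r_mid + band || rho2 < r_mid - band) {
          rho_c <- min(max(rho2, r_mid - band), r_mid + band)
          ang <- atan2(y - g$center[2], x - g$center[1])
          x <- g$center[1] + rho_c * cos(ang)
          y <- g$center[2] + rho_c * sin(ang)
        }
      }
    }
  }

  keep <- (S + 1L):K
  long <- purrr::map(ids, function(f) {
    tibble::tibble(frame = seq_along(keep) - 1L,
                   time = round(t_ext[keep], 10),
                   id = f,
                   x = px[keep, f], y = py[keep, f], valid = TRUE)
  })
  ts <- new_trajectory_set(dplyr::bind_rows(long), g, dt)

  scripted <- purrr::map(ids, function(f) {
    tibble::tibble(frame = seq_along(keep) - 1L,
                   time = round(t_ext[keep], 10), id = f,
                   phi = phi[keep, f], speed = spd[keep, f])
  }) |> dplyr::bind_rows()

  # realized mid-turn instants from the scripted headings
  sched <- purrr::map(ids, function(f) {
    pos_psi <- atan2(py[keep, f] - g$center[2], px[keep, f] - g$center[1])
    s <- sin(wrap_angle(phi[keep, f] - pos_psi))
    root <- f
    while (root %in% names(config$influence_graph)) {
      root <- as.character(config$influence_graph[[root]]$influencer)
    }
    t_sched <- uturn_times[match(root, roots)] + shift[f] * dt
    dur_root <- turn_dur[root]
    tt <- t_ext[keep]
    cross <- which(sign(s[-length(s)]) != sign(s[-1]) & sign(s[-1]) != 0)
    if (!length(cross)) {
      return(tibble::tibble(id = f, t_scheduled = t_sched,
                            t_m_true = NA_real_))
    }
    mid_target <- t_sched + dur_root / 2
    best <- cross[which.min(abs(tt[cross] - mid_target))]
    tibble::tibble(id = f, t_scheduled = t_sched, t_m_true = tt[best])
  }) |> dplyr::bind_rows()

  infl <- if (length(config$influence_graph)) {
    tibble::tibble(
      follower = names(config$influence_graph),
      influencer = vapply(config$influence_graph,
                          function(l) as.character(l$influencer), ""),
      delay_frames = vapply(config$influence_graph,
                            function(l) as.integer(l$delay), 1L),
      total_shift = shift[names(config$influence_graph)])
  } else {
    tibble::tibble(follower = character(), influencer = character(),
                   delay_frames = integer(), total_shift = integer())
  }

  list(trajectories = ts,
       truth = list(influence = infl, uturn_schedule = sched,
                    headings = scripted))
}

#' Canonical labeled fixtures
#'
#' Writes (or returns in memory) the fixture suite used throughout
#' validation: a leader-follower pair with lag 20 frames (noiseless and
#' with kappa = 100 heading noise), a 5-fish chain
#' (1 <- 2 <- 3 <- 4 <- 5 with staggered lags), a 5-fish star (all copy
#' fish 1), and a 5-fish group of independent turners (no influence).
#'
#' @param dir output directory, or `NULL` to skip writing files.
#' @param seed RNG seed forwarded to every fixture.
#' @return named list of [simulate_school()] outputs (invisible when
#'   writing). With `dir`, each fixture is written as
#'   `<name>_trajectories.csv` plus `<name>_ground_truth.json`.
#' @export
make_fixture_suite <- function(dir = NULL, seed = 1L) {
  fixtures <- list(
    # pairs run longer than the group fixtures: delay-recovery summaries
    # are per-frame statistics and benefit from a long stationary record
    pair_lag20 = sim_config(
      n_fish = 2, duration = 30, uturn_times = 15,
      influence_graph = list(`2` = list(influencer = "1", delay = 20)),
      kappa = Inf, seed = seed),
    pair_lag20_noisy = sim_config(
      n_fish = 2, duration = 30, uturn_times = 15,
      influence_graph = list(`2` = list(influencer = "1", delay = 20)),
      kappa = 100, seed = seed + 1L),
    chain5 = sim_config(
      n_fish = 5, duration = 12, uturn_times = 6,
      influence_graph = list(
        `2` = list(influencer = "1", delay = 10),
        `3` = list(influencer = "2", delay = 12),
        `4` = list(influencer = "3", delay = 14),
        `5` = list(influencer = "4", delay = 16)),
      kappa = 100, seed = seed + 2L),
    # all star followers share one lag: any alignment between two
    # followers of the hub then sits at delay zero, below the
    # reaction-time floor, so only the direct edges to fish 1 survive
    # the gates (individuality separates the followers' trajectories)
    star5 = sim_config(
      n_fish = 5, duration = 12, uturn_times = 6,
      influence_graph = list(
        `2` = list(influencer = "1", delay = 10),
        `3` = list(influencer = "1", delay = 10),
        `4` = list(influencer = "1", delay = 10),
        `5` = list(influencer = "1", delay = 10)),
      kappa = 100, own_wiggle = 0.2, seed = seed + 3L),
    no_influence5 = sim_config(
      n_fish = 5, duration = 12,
      uturn_times = c(5.6, 5.8, 6.0, 6.2, 6.4),
      influence_graph = list(), kappa = 100, seed = seed + 4L))
  out <- purrr::map(fixtures, simulate_school)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      write_trajectories(out[[nm]]$trajectories,
                         file.path(dir, paste0(nm, "_trajectories.csv")))
      truth <- out[[nm]]$truth
      jsonlite::write_json(
        list(influence = truth$influence,
             uturn_schedule = truth$uturn_schedule),
        file.path(dir, paste0(nm, "_ground_truth.json")),
        dataframe = "rows", auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(out)
}

# von Mises deviates redrawn every `interval` frames and held in between
draw_heading_noise <- function(K, kappa, interval) {
  if (!is.finite(kappa)) return(numeric(K))
  n_draw <- ceiling(K / interval)
  rep(rvonmises(n_draw, 0, kappa), each = interval)[seq_len(K)]
}


# seeded heading wiggle: renewal jump process (kick times Poisson with
# mean interval `kick_interval` seconds, levels iid N(0, amp)) plus a
# small smooth Gaussian dither that breaks exact correlation ties between
# kicks
draw_wiggle <- function(K, amp, kick_interval, dt) {
  if (amp == 0) return(numeric(K))
  mu_frames <- max(kick_interval / dt, 2)
  n_kick <- ceiling(2 * K / mu_frames) + 5
  # quasi-regular kick times; successive kick levels alternate sign with
  # jittered magnitude (the left/right zigzag of burst-and-coast swimming)
  gaps <- pmax(1, round(runif(n_kick, 0.8, 1.2) * mu_frames))
  kick_at <- cumsum(gaps)
  kick_at <- kick_at[kick_at <= K]
  sgn <- rep_len(c(1, -1), length(kick_at) + 1) * sample(c(1, -1), 1)
  # jittered kick magnitude: two independent fish then rarely hold
  # near-identical heading offsets even when their zigzag phases agree,
  # which keeps spurious correlations between non-interacting fish down.
  levels <- sgn * abs(rnorm(length(kick_at) + 1, amp, 0.5 * amp))
  idx <- findInterval(seq_len(K), kick_at) + 1
  kicks <- levels[idx]
  # fast fine dither (sd 0.25 rad, ~1.5-frame correlation): the yaw of
  # body undulation riding on the heading. Followers copy it along with
  # the rest of the heading, so it sharpens the correlation peak at the
  # true lag while setting a mismatch floor between fish that do not
  # interact (independent dithers rarely cancel)
  kicks + draw_dither(K, 0.25)
}

# smooth fast Gaussian heading component (~1.5-frame correlation time)
draw_dither <- function(K, sd_rad) {
  if (sd_rad == 0) return(numeric(K))
  half <- 5L
  kern <- exp(-((-half:half)^2) / (2 * 1.5^2))
  kern <- kern / sum(kern)
  raw <- rnorm(K + 2 * half)
  sm <- as.numeric(stats::filter(raw, kern, sides = 2))
  out <- sd_rad * sm[(half + 1):(half + K)] / sqrt(sum(kern^2))
  # clamp the tails: heading excursions of a swimming fish are bounded,
  # and bounded extremes keep the moving-average maxima (the U-turn
  # bound thresholds) stable against the span they are computed over
  pmin(pmax(out, -1.5 * sd_rad), 1.5 * sd_rad)
}
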