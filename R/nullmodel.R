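#' Null-model configuration
#'
#' Parameters of the trajectory-bootstrap null model: artificial collective
#' U-turns are assembled from independently sampled individual U-turn
#' tracks that are rotated so every fish turns in the upper part of the
#' tank (angular position within `xi_range` of `pi/2`), time-shifted so
#' every fish turns within `zeta_range` seconds of time zero, and mirrored
#' where needed so all group members circulate in the same direction.
#'
#' @param xi_range half-width of the turn-position jitter (rad);
#'   default `pi/12`.
#' @param zeta_range half-width of the turn-time jitter (s); default 1.
#' @param group_size fish per artificial U-turn; default 5.
#' @param n_events number of artificial U-turns; default 1000.
#' @return an object of class `null_config`.
#' @export
null_config <- function(xi_range = pi / 12, zeta_range = 1,
                        group_size = 5, n_events = 1000) {
  stopifnot(xi_range > 0, xi_range < pi, zeta_range > 0, group_size >= 2,
            n_events >= 1)
  structure(list(xi_range = xi_range, zeta_range = zeta_range,
                 group_size = as.integer(group_size),
                 n_events = as.integer(n_events)),
            class = "null_config")
}

#' Build the pool of individual U-turn tracks
#'
#' Extracts, for every fish of every detected collective U-turn, its polar
#' track over the event window extended on each side by one event duration
#' or 3 s, whichever is larger (clipped to the record), together with its
#' individual turn instant `T_i` and circulation direction before the
#' turn. The margin guarantees that recombined tracks still share a usable
#' time span after the null model's +-1 s time shifts, and that artificial
#' U-turns are long enough for the delay recursion to activate. This pool
#' is what the null model resamples.
#'
#' @param ts the `trajectory_set` the events were detected in.
#' @param events an `uturn_events` tibble from [detect_uturns()].
#' @return tibble with one row per (event, fish): `source_event,
#'   source_fish, T_i, direction_before, track` (list column of tibbles
#'   `time, rho, psi`).
#' @export
uturn_track_pool <- function(ts, events) {
  pol <- to_polar(ts)
  ev <- tibble::as_tibble(events)
  rows <- purrr::pmap(
    ev[, c("event_id", "id", "t_m_i", "t_s", "t_e", "direction_before")],
    function(event_id, id, t_m_i, t_s, t_e, direction_before) {
      dur <- max(t_e - t_s, 3)
      tr <- pol[pol$id == id & pol$time >= t_s - dur &
                  pol$time <= t_e + dur & pol$valid, ]
      tr <- tr[order(tr$time), ]
      tibble::tibble(source_event = event_id, source_fish = id,
                     T_i = t_m_i, direction_before = direction_before,
                     track = list(tr[, c("time", "rho", "psi")]))
    })
  dplyr::bind_rows(rows)
}

#' Rotate a polar track so its turn happens near the top of the tank
#'
#' Adds `-psi(T_i) + pi/2 + xi` to every angular position (radii are
#' untouched), relocating the position at the turn instant to angle
#' `pi/2 + xi`.
#'
#' @param track tibble `time, rho, psi`.
#' @param T_i turn instant (s), must lie inside the track.
#' @param xi rotation jitter (rad).
#' @return the rotated track.
#' @export
rotate_track <- function(track, T_i, xi) {
  if (T_i < min(track$time) || T_i > max(track$time)) {
    stop("turn instant outside the track", call. = FALSE)
  }
  k <- which.min(abs(track$time - T_i))
  track$psi <- wrap_angle(track$psi - track$psi[k] + pi / 2 + xi)
  track
}

#' Shift a track's clock so its turn happens near time zero
#'
#' @param track tibble `time, rho, psi`.
#' @param T_i turn instant (s).
#' @param zeta time jitter (s); the new turn time equals `zeta`.
#' @return the shifted track.
#' @export
shift_track <- function(track, T_i, zeta) {
  track$time <- track$time - T_i + zeta
  track
}

#' Mirror a polar track across the vertical axis
#'
#' `psi -> pi - psi` reflects the scene through the vertical axis of the
#' tank: circulation direction flips (clockwise and anticlockwise swap)
#' while the relocated turn region near the top maps to itself. Applying
#' it twice is the identity.
#'
#' @param track tibble `time, rho, psi`.
#' @return the mirrored track.
#' @export
mirror_track <- function(track) {
  track$psi <- wrap_angle(pi - track$psi)
  track
}

#' Assemble one artificial collective U-turn
#'
#' Samples `group_size` distinct source events (uniformly, without
#' replacement) and one track from each, picks one of them as the
#' reference, rotates each track by `-psi(T_i) + pi/2 + xi_i`, shifts each
#' clock by `-T_i + zeta_i` (with `zeta_i` snapped to the frame grid so
#' all tracks stay on a common clock), mirrors tracks whose circulation
#' direction differs from the reference's, and truncates everything to the
#' common time span. Draws consume the current RNG stream in a fixed
#' order: events, fish, reference, xi's, zeta's.
#'
#' @param pool tibble from [uturn_track_pool()].
#' @param config a [null_config()].
#' @param geometry a [ring_geometry()] for rebuilding Cartesian positions.
#' @param dt frame interval (s).
#' @return list with `trajectories` (a `trajectory_set` with fish ids
#'   `"1".."group_size"`) and `provenance` (tibble `id, source_event,
#'   source_fish, xi, zeta, mirrored`).
#' @export
build_artificial_uturn <- function(pool, config = null_config(),
                                   geometry = ring_geometry(), dt = 0.02) {
  evs <- unique(pool$source_event)
  if (length(evs) < config$group_size) {
    stop("pool has fewer source events than the group size", call. = FALSE)
  }
  chosen_ev <- sample(evs, config$group_size)
  picks <- purrr::map_int(chosen_ev, function(e) {
    cand <- which(pool$source_event == e)
    if (length(cand) == 1L) cand else sample(cand, 1L)
  })
  ref <- sample(config$group_size, 1L)
  xi <- runif(config$group_size, -config$xi_range, config$xi_range)
  zeta <- round(runif(config$group_size, -config$zeta_range,
                      config$zeta_range) / dt) * dt
  rows <- pool[picks, ]
  tracks <- purrr::map(seq_len(config$group_size), function(i) {
    tr <- rotate_track(rows$track[[i]], rows$T_i[i], xi[i])
    shift_track(tr, rows$T_i[i], zeta[i])
  })
  mirrored <- rows$direction_before != rows$direction_before[ref]
  tracks <- purrr::map2(tracks, mirrored, function(tr, m) {
    if (m) mirror_track(tr) else tr
  })
  t_lo <- max(purrr::map_dbl(tracks, ~ min(.x$time)))
  t_hi <- min(purrr::map_dbl(tracks, ~ max(.x$time)))
  if (t_hi - t_lo < 10 * dt) {
    stop("sampled tracks share too little common time span", call. = FALSE)
  }
  grid <- seq(ceiling(round(t_lo / dt, 6)) * dt,
              floor(round(t_hi / dt, 6)) * dt, by = dt)
  long <- purrr::imap(tracks, function(tr, i) {
    # tracks are on the dt grid after snapping; align by nearest frame
    idx <- round((tr$time - grid[1]) / dt) + 1
    keep <- idx >= 1 & idx <= length(grid)
    out <- tibble::tibble(frame = NA_integer_, time = grid,
                          id = as.character(i), rho = NA_real_,
                          psi = NA_real_, valid = FALSE)
    out$rho[idx[keep]] <- tr$rho[keep]
    out$psi[idx[keep]] <- tr$psi[keep]
    out$valid[idx[keep]] <- TRUE
    out$frame <- seq_along(grid) - 1L
    out
  })
  polar <- dplyr::bind_rows(long)
  polar$rho[!polar$valid] <- 0
  polar$psi[!polar$valid] <- 0
  ts <- from_polar(polar, geometry, dt)
  ts$x[!polar$valid] <- NA_real_
  ts$y[!polar$valid] <- NA_real_
  prov <- tibble::tibble(id = as.character(seq_len(config$group_size)),
                         source_event = rows$source_event,
                         source_fish = rows$source_fish,
                         xi = xi, zeta = zeta, mirrored = mirrored,
                         reference = seq_len(config$group_size) == ref)
  list(trajectories = ts, provenance = prov)
}

#' Generate and analyze an ensemble of artificial collective U-turns
#'
#' Repeats [build_artificial_uturn()] `n_events` times and, when
#' `analyze = TRUE`, pushes every artificial U-turn through the identical
#' detection / delay-extraction / influence pipeline used for real data.
#'
#' @inheritParams build_artificial_uturn
#' @param analysis_cfg an [analysis_config()] for the influence stage.
#' @param analyze run the full pipeline on each event?
#' @param seed integer seed; the ensemble is fully determined by it.
#' @return list with `events` (list of `build_artificial_uturn()` outputs)
#'   and `analyses` (list of `uturn_analysis`, `NULL` when
#'   `analyze = FALSE`). Events whose assembled tracks are unusable (too
#'   little overlap) are skipped and counted in `n_failed`.
#' @export
generate_null_ensemble <- function(pool, config = null_config(),
                                   geometry = ring_geometry(), dt = 0.02,
                                   analysis_cfg = analysis_config(),
                                   analyze = TRUE, seed = 1L) {
  set.seed(seed)
  events <- list()
  analyses <- list()
  n_failed <- 0L
  made <- 0L
  while (made < config$n_events) {
    ev <- tryCatch(build_artificial_uturn(pool, config, geometry, dt),
                   error = function(e) NULL)
    if (is.null(ev)) {
      n_failed <- n_failed + 1L
      if (n_failed > 20L * config$n_events) {
        stop("null-model assembly keeps failing; pool too sparse",
             call. = FALSE)
      }
      next
    }
    made <- made + 1L
    events[[made]] <- ev
    if (analyze) {
      analyses[[made]] <- tryCatch(
        analyze_uturn(interpolate_gaps(ev$trajectories),
                      config = analysis_cfg),
        error = function(e) NULL)
    }
  }
  list(events = events,
       analyses = if (analyze) analyses else NULL,
       n_failed = n_failed)
}
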