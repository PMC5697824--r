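#' Per-frame kinematics: velocity, heading, wall incidence
#'
#' Velocities are central finite differences over one frame (one-sided at
#' the record ends). The heading `phi = atan2(vy, vx)` is defined where the
#' speed is at least `speed_floor`; below the floor the last defined heading
#' is carried forward, which keeps `atan2` noise at near-zero speed out of
#' the correlation analysis. The wall-incidence angle is
#' `theta_w = wrap(phi - psi)` with `psi` the angular position about the
#' tank center: `|theta_w|` is about `pi/2` when swimming along the wall and
#' the sign of `sin(theta_w)` encodes the circulation direction
#' (positive = anticlockwise).
#'
#' @param ts a `trajectory_set` (gap-interpolated; see [interpolate_gaps()]).
#' @param speed_floor minimum speed (mm/s) at which a fresh heading is
#'   computed; default 1.
#' @return a tibble `frame, time, id, x, y, vx, vy, speed, phi, theta_w,
#'   psi, rho, valid`, classed `kinematics` and carrying `dt` and the
#'   geometry as attributes.
#' @export
compute_kinematics <- function(ts, speed_floor = 1) {
  stopifnot(speed_floor >= 0)
  dt <- traj_dt(ts)
  pol <- to_polar(ts)
  df <- dplyr::left_join(tibble::as_tibble(ts),
                         pol[, c("frame", "id", "rho", "psi")],
                         by = c("frame", "id"))
  pieces <- lapply(split(df, df$id), function(tr) {
    tr <- tr[order(tr$time), ]
    n <- nrow(tr)
    x <- tr$x; y <- tr$y
    x[!tr$valid] <- NA_real_; y[!tr$valid] <- NA_real_
    vx <- central_diff(x, dt)
    vy <- central_diff(y, dt)
    speed <- sqrt(vx^2 + vy^2)
    phi <- ifelse(!is.na(speed) & speed >= speed_floor, atan2(vy, vx),
                  NA_real_)
    phi <- carry_forward(phi)
    if (all(is.na(phi))) {
      stop("fish ", tr$id[1], ": speed never reaches the floor, heading ",
           "undefined over the whole track", call. = FALSE)
    }
    tr$vx <- vx; tr$vy <- vy; tr$speed <- speed
    tr$phi <- phi
    tr$theta_w <- wrap_angle(phi - tr$psi)
    tr
  })
  out <- dplyr::bind_rows(pieces)
  out <- out[, c("frame", "time", "id", "x", "y", "vx", "vy", "speed",
                 "phi", "theta_w", "psi", "rho", "valid")]
  structure(dplyr::arrange(out, .data$id, .data$time),
            class = c("kinematics", class(tibble::tibble())),
            dt = dt, geometry = traj_geometry(ts))
}

central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  v <- rep(NA_real_, n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v
}

carry_forward <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- cumsum(!is.na(x))
  filled <- ifelse(idx == 0, NA_real_, x[!is.na(x)][pmax(idx, 1L)])
  filled
}

#' Group polarization
#'
#' The polarization order parameter `P = ||sum_i e_i|| / N` of `N` unit
#' heading vectors: 1 when all headings agree, 0 when they cancel.
#'
#' `polarization()` takes a vector of headings at one instant;
#' `polarization_series()` evaluates it frame by frame from a kinematics
#' table, returning `NA` at frames where any heading is undefined.
#'
#' @param phi numeric vector of headings (rad); `NA` makes the result `NA`.
#' @return scalar in `[0, 1]`, or `NA`.
#' @examples
#' polarization(rep(0.3, 5)) # 1
#' polarization(c(0, pi))    # 0
#' @export
polarization <- function(phi) {
  if (length(phi) == 0 || anyNA(phi)) return(NA_real_)
  sqrt(sum(cos(phi))^2 + sum(sin(phi))^2) / length(phi)
}

#' @rdname polarization
#' @param kin a `kinematics` tibble from [compute_kinematics()].
#' @return `polarization_series()`: tibble `frame, time, polarization`.
#' @export
polarization_series <- function(kin) {
  kin |>
    dplyr::group_by(.data$frame, .data$time) |>
    dplyr::summarise(polarization = polarization(.data$phi),
                     .groups = "drop") |>
    dplyr::arrange(.data$time)
}

#' Pairwise relative geometry
#'
#' For every ordered pair (focal `i`, neighbor `j`) at every frame where
#' both are valid: relative position `u_ij = u_j - u_i`, distance
#' `d_ij = ||u_ij||`, viewing angle `theta_ij` (bearing of the neighbor
#' relative to the focal's heading), heading difference
#' `phi_ij = wrap(phi_j - phi_i)`, and relative velocity. The viewing angle
#' is set to `NA` for coincident positions.
#'
#' @param kin a `kinematics` tibble.
#' @return tibble `frame, time, focal, neighbor, ux, uy, d, theta_view,
#'   phi_diff, dvx, dvy`.
#' @export
pair_geometry <- function(kin) {
  df <- tibble::as_tibble(kin)[, c("frame", "time", "id", "x", "y",
                                   "vx", "vy", "phi", "valid")]
  foc <- dplyr::rename(df, focal = "id", xi = "x", yi = "y",
                       vxi = "vx", vyi = "vy", phii = "phi", vi = "valid")
  nb <- dplyr::rename(df, neighbor = "id", xj = "x", yj = "y",
                      vxj = "vx", vyj = "vy", phij = "phi", vj = "valid")
  out <- dplyr::inner_join(foc, nb, by = c("frame", "time"),
                           relationship = "many-to-many") |>
    dplyr::filter(.data$focal != .data$neighbor, .data$vi, .data$vj) |>
    dplyr::mutate(
      ux = .data$xj - .data$xi,
      uy = .data$yj - .data$yi,
      d = sqrt(.data$ux^2 + .data$uy^2),
      theta_view = dplyr::if_else(.data$d > 0,
                                  wrap_angle(atan2(.data$uy, .data$ux) - .data$phii),
                                  NA_real_),
      phi_diff = wrap_angle(.data$phij - .data$phii),
      dvx = .data$vxj - .data$vxi,
      dvy = .data$vyj - .data$vyi)
  out[, c("frame", "time", "focal", "neighbor", "ux", "uy", "d",
          "theta_view", "phi_diff", "dvx", "dvy")]
}

#' Burst segmentation of a speed series
#'
#' Burst-and-coast swimmers alternate brief accelerations with passive
#' glides. A burst here is a maximal interval where the acceleration of the
#' smoothed speed exceeds `accel_threshold`, extended backward to the
#' preceding local speed minimum and forward to the next local speed
#' maximum. The operational rule (threshold on smoothed acceleration) is
#' this package's own; thresholds are configurable.
#'
#' @param kin a `kinematics` tibble.
#' @param accel_threshold acceleration threshold, mm/s^2 (default 300).
#' @param smooth_window centered moving-average window (frames, default 5).
#' @return object of class `burst_segmentation`: list with `intervals`
#'   (tibble `id, onset_frame, offset_frame, onset_time, offset_time`) and
#'   `frames` (tibble `frame, time, id, bursting`).
#' @export
detect_bursts <- function(kin, accel_threshold = 300, smooth_window = 5) {
  stopifnot(accel_threshold > 0)
  dt <- attr(kin, "dt")
  df <- tibble::as_tibble(kin)
  res <- lapply(split(df, df$id), function(tr) {
    tr <- tr[order(tr$time), ]
    n <- nrow(tr)
    if (n < smooth_window || n < 3) {
      stop("speed series shorter than the smoothing window", call. = FALSE)
    }
    sm <- moving_average(tr$speed, smooth_window)
    acc <- central_diff(sm, dt)
    hot <- !is.na(acc) & acc > accel_threshold
    r <- rle(hot)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    bursting <- rep(FALSE, n)
    iv <- list()
    for (g in which(r$values)) {
      on <- starts[g]; off <- ends[g]
      # extend back to preceding local minimum of smoothed speed
      while (on > 1L && sm[on - 1L] < sm[on]) on <- on - 1L
      # extend forward to next local maximum
      while (off < n && sm[off + 1L] > sm[off]) off <- off + 1L
      bursting[on:off] <- TRUE
      iv[[length(iv) + 1L]] <- c(on, off)
    }
    # merge overlapping extended intervals via the frame mask
    rr <- rle(bursting)
    e2 <- cumsum(rr$lengths); s2 <- e2 - rr$lengths + 1L
    ivs <- which(rr$values)
    intervals <- tibble::tibble(
      id = rep(tr$id[1], length(ivs)),
      onset_frame = tr$frame[s2[ivs]],
      offset_frame = tr$frame[e2[ivs]],
      onset_time = tr$time[s2[ivs]],
      offset_time = tr$time[e2[ivs]])
    list(intervals = intervals,
         frames = tibble::tibble(frame = tr$frame, time = tr$time,
                                 id = tr$id, bursting = bursting))
  })
  structure(list(intervals = dplyr::bind_rows(lapply(res, `[[`, "intervals")),
                 frames = dplyr::bind_rows(lapply(res, `[[`, "frames"))),
            class = "burst_segmentation")
}

#' @export
print.burst_segmentation <- function(x, ...) {
  cat(sprintf("<burst_segmentation> %d bursts across %d fish\n",
              nrow(x$intervals), length(unique(x$frames$id))))
  invisible(x)
}

#' Broom-style tidier for burst segmentations
#' @param x a `burst_segmentation`.
#' @param ... unused.
#' @return the burst interval tibble.
#' @export
tidy.burst_segmentation <- function(x, ...) x$intervals

#' Overlap between bursting activity and influence
#'
#' For each influence record (t, focal i, neighbor j, delay tau), checks
#' whether the influential neighbor j was bursting at the emission time
#' `t - tau`. The per-fish statistic is the ratio
#' `P(j bursting at t - tau | j influential) / P(j bursting)`; values near 1
#' mean influence times are unrelated to bursting. Also returns the raster
#' rows used for burst/influence timelines: each fish's own bursting frames
#' and, offset by -0.5, the frames where its influencer was bursting at
#' emission (on ties the influencer with the highest id is shown).
#'
#' @param bursts a `burst_segmentation`.
#' @param records an influence-record tibble (see [identify_influential()]).
#' @return list with `stats` (tibble `id, n_records, n_skipped,
#'   p_burst_given_influence, burst_fraction, overlap_ratio`) and `raster`
#'   (tibble `time, row, fish, kind, influencer`).
#' @export
burst_influence_overlap <- function(bursts, records) {
  fr <- bursts$frames
  ids <- sort(unique(fr$id))
  burst_frac <- fr |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(burst_fraction = mean(.data$bursting), .groups = "drop")
  dt <- if (nrow(fr) > 1) {
    stats::median(diff(sort(unique(fr$time))))
  } else {
    NA_real_
  }
  if (nrow(records) == 0) {
    st <- tibble::tibble(id = ids, n_records = 0L, n_skipped = 0L,
                         p_burst_given_influence = NA_real_) |>
      dplyr::left_join(burst_frac, by = "id") |>
      dplyr::mutate(overlap_ratio = NA_real_)
    return(list(stats = st, raster = empty_raster(fr)))
  }
  rec <- records |>
    dplyr::mutate(t_emit = .data$time - .data$tau)
  # match emission times to the neighbor's frame grid
  key <- fr |>
    dplyr::rename(neighbor = "id", t_emit = "time",
                  emit_bursting = "bursting") |>
    dplyr::select("neighbor", "t_emit", "emit_bursting")
  rec <- rec |>
    dplyr::mutate(t_emit = round(.data$t_emit / dt) * dt) |>
    dplyr::left_join(dplyr::mutate(key, t_emit = round(.data$t_emit / dt) * dt),
                     by = c("neighbor", "t_emit"))
  skipped <- is.na(rec$emit_bursting)
  kept <- rec[!skipped, ]
  st <- kept |>
    dplyr::group_by(id = .data$neighbor) |>
    dplyr::summarise(n_records = dplyr::n(),
                     p_burst_given_influence = mean(.data$emit_bursting),
                     .groups = "drop")
  n_skip <- rec[skipped, ] |>
    dplyr::count(id = .data$neighbor, name = "n_skipped")
  st <- tibble::tibble(id = ids) |>
    dplyr::left_join(st, by = "id") |>
    dplyr::left_join(n_skip, by = "id") |>
    dplyr::left_join(burst_frac, by = "id") |>
    dplyr::mutate(
      n_records = dplyr::coalesce(.data$n_records, 0L),
      n_skipped = dplyr::coalesce(.data$n_skipped, 0L),
      overlap_ratio = dplyr::if_else(
        .data$burst_fraction > 0 & .data$n_records > 0,
        .data$p_burst_given_influence / .data$burst_fraction, NA_real_))
  # raster: own bursts at row index(i); influencer-burst flags at index(i)-0.5
  row_of <- stats::setNames(seq_along(ids), ids)
  own <- fr |>
    dplyr::filter(.data$bursting) |>
    dplyr::transmute(time = .data$time, row = row_of[.data$id],
                     fish = .data$id, kind = "burst",
                     influencer = NA_character_)
  infl <- kept |>
    dplyr::filter(.data$emit_bursting) |>
    dplyr::group_by(.data$time, .data$focal) |>
    dplyr::slice_max(.data$neighbor, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(time = .data$time, row = row_of[.data$focal] - 0.5,
                     fish = .data$focal, kind = "influencer_burst",
                     influencer = .data$neighbor)
  list(stats = st, raster = dplyr::bind_rows(own, infl))
}

empty_raster <- function(fr) {
  tibble::tibble(time = numeric(), row = numeric(), fish = character(),
                 kind = character(), influencer = character())
}
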