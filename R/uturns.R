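#' Detect individual U-turn instants
#'
#' A fish's circulation direction in the ring is the sign of
#' `sin(theta_w)`. A candidate turn instant `t_m` is a sign change of
#' `sin(theta_w)` that is persistent: the mean of `sin(theta_w)` over the
#' `persistence` frames on each side must exceed `min_abs_sin` in absolute
#' value, with opposite signs. Brief jitter around zero mid-lap therefore
#' does not register.
#'
#' @param kin a `kinematics` tibble from [compute_kinematics()].
#' @param persistence window length in frames on each side (default 25).
#' @param min_abs_sin minimum mean `|sin(theta_w)|` on each side
#'   (default 0.5).
#' @return tibble `id, frame_m, t_m, direction_before, direction_after`
#'   with directions in `c("clockwise", "anticlockwise")`; zero rows if no
#'   turn is found.
#' @export
detect_individual_uturns <- function(kin, persistence = 25, min_abs_sin = 0.5) {
  stopifnot(persistence >= 1, min_abs_sin >= 0)
  df <- tibble::as_tibble(kin)
  out <- lapply(split(df, df$id), function(tr) {
    tr <- tr[order(tr$time), ]
    s <- sin(tr$theta_w)
    n <- length(s)
    hits <- integer(0)
    before_pos <- logical(0)
    if (n >= 2 * persistence) {
      sgn <- sign(s)
      cross <- which(sgn[-n] != 0 & sgn[-1] != 0 & sgn[-n] != sgn[-1])
      s0 <- ifelse(is.na(s), 0, s)
      cs <- cumsum(c(0, s0))
      cna <- cumsum(c(0, is.na(s))) # windows touching NA frames are skipped
      for (k in cross) {
        if (k - persistence + 1 < 1 || k + persistence > n) next
        if (cna[k + 1 + persistence] - cna[k + 1 - persistence] > 0) next
        m_before <- (cs[k + 1] - cs[k + 1 - persistence]) / persistence
        m_after <- (cs[k + 1 + persistence] - cs[k + 1]) / persistence
        if (abs(m_before) > min_abs_sin && abs(m_after) > min_abs_sin &&
            sign(m_before) != sign(m_after)) {
          hits <- c(hits, k)
          before_pos <- c(before_pos, m_before > 0)
        }
      }
    }
    if (!length(hits)) {
      return(tibble::tibble(id = character(), frame_m = numeric(),
                            t_m = numeric(), direction_before = character(),
                            direction_after = character()))
    }
    tibble::tibble(
      id = tr$id[1],
      frame_m = tr$frame[hits],
      t_m = tr$time[hits],
      direction_before = ifelse(before_pos, "anticlockwise", "clockwise"),
      direction_after = ifelse(before_pos, "clockwise", "anticlockwise"))
  })
  dplyr::bind_rows(out)
}

#' Bound one individual U-turn
#'
#' Start/end thresholds are the maxima of the absolute centered moving
#' average (window `ma_window` frames) of `sin(theta_w)` over the `span`
#' frames before (resp. after) the turn instant `t_m`. The start `t_s` is
#' found by stepping backward from `t_m` until `|sin(theta_w)|` first
#' exceeds the start threshold; the end `t_e` by stepping forward until it
#' exceeds the end threshold. The sine (rather than the raw angle) is
#' used because it saturates at 1 whenever the fish is wall-parallel:
#' its maxima are capped, so the thresholds — and with them the bounds —
#' are insensitive to the span they are computed over, which the raw
#' angle's unbounded excursions are not.
#'
#' @param kin a `kinematics` tibble.
#' @param fish fish id.
#' @param t_m turn instant (s), e.g. from [detect_individual_uturns()].
#' @param span frames used on each side when computing thresholds
#'   (default 50, i.e. 1 s at 50 Hz).
#' @param ma_window moving-average window in frames (default 5).
#' @return one-row tibble `id, t_s, t_m, t_e, thr_s, thr_e`.
#' @export
uturn_bounds <- function(kin, fish, t_m, span = 50, ma_window = 5) {
  tr <- dplyr::filter(tibble::as_tibble(kin), .data$id == fish)
  tr <- tr[order(tr$time), ]
  m <- which.min(abs(tr$time - t_m))
  n <- nrow(tr)
  if (m - span < 1 || m + span > n) {
    stop("need at least ", span, " frames on each side of the turn instant",
         call. = FALSE)
  }
  before <- sin(tr$theta_w[(m - span):(m - 1)])
  after <- sin(tr$theta_w[(m + 1):(m + span)])
  thr_s <- max(abs(moving_average(before, ma_window)))
  thr_e <- max(abs(moving_average(after, ma_window)))
  aw <- abs(sin(tr$theta_w))
  i_s <- m
  while (i_s >= 1 && aw[i_s] <= thr_s) i_s <- i_s - 1L
  if (i_s < 1) {
    stop("start threshold never exceeded before the turn instant",
         call. = FALSE)
  }
  i_e <- m
  while (i_e <= n && aw[i_e] <= thr_e) i_e <- i_e + 1L
  if (i_e > n) {
    stop("end threshold never exceeded after the turn instant",
         call. = FALSE)
  }
  tibble::tibble(id = fish, t_s = tr$time[i_s], t_m = tr$time[m],
                 t_e = tr$time[i_e], thr_s = thr_s, thr_e = thr_e)
}

#' Detect collective U-turns
#'
#' Finds individual turn instants for every fish, bounds each turn, and
#' associates individual turns of different fish into collective events
#' when their turn instants fall within `assoc_window` seconds of each
#' other and share the same direction change. Events in which any group
#' member lacks a matched individual turn are dropped (reported in the
#' `"incomplete"` attribute).
#'
#' @inheritParams detect_individual_uturns
#' @param assoc_window association window in seconds (default 3).
#' @param span,ma_window passed to [uturn_bounds()].
#' @return an `uturn_events` tibble, one row per fish per event:
#'   `event_id, id, t_s_i, t_m_i, t_e_i, thr_s, thr_e, direction_before,
#'   direction_after, turning_rank, t_s, t_e` where `t_s = min_i t_s_i` and
#'   `t_e = max_i t_e_i` are the collective start and end.
#' @export
detect_uturns <- function(kin, persistence = 25, min_abs_sin = 0.5,
                          assoc_window = 3, span = 50, ma_window = 5) {
  cand <- detect_individual_uturns(kin, persistence, min_abs_sin)
  ids <- unique(tibble::as_tibble(kin)$id)
  n_fish <- length(ids)
  empty <- tibble::tibble(
    event_id = integer(), id = character(), t_s_i = numeric(),
    t_m_i = numeric(), t_e_i = numeric(), thr_s = numeric(),
    thr_e = numeric(), direction_before = character(),
    direction_after = character(), turning_rank = integer(),
    t_s = numeric(), t_e = numeric())
  if (nrow(cand) == 0) {
    return(structure(empty, class = c("uturn_events", class(empty)),
                     incomplete = empty))
  }
  cand <- dplyr::arrange(cand, .data$t_m)
  # single-linkage clustering on t_m within the association window,
  # split further by direction change
  grp <- cumsum(c(1, diff(cand$t_m) > assoc_window))
  cand$cluster <- paste(grp, cand$direction_before, cand$direction_after)
  events <- list()
  incomplete <- list()
  eid <- 0L
  for (cl in split(cand, cand$cluster)) {
    # one turn per fish: keep the first candidate of each fish
    cl <- cl |>
      dplyr::group_by(.data$id) |>
      dplyr::slice_min(.data$t_m, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    rows <- purrr::map(seq_len(nrow(cl)), function(r) {
      tryCatch(uturn_bounds(kin, cl$id[r], cl$t_m[r], span, ma_window),
               error = function(e) NULL)
    })
    ok <- !vapply(rows, is.null, logical(1))
    cl <- cl[ok, ]
    if (!nrow(cl)) next
    b <- dplyr::bind_rows(rows[ok])
    ev <- tibble::tibble(
      id = cl$id, t_s_i = b$t_s, t_m_i = b$t_m, t_e_i = b$t_e,
      thr_s = b$thr_s, thr_e = b$thr_e,
      direction_before = cl$direction_before,
      direction_after = cl$direction_after)
    if (nrow(ev) < n_fish) {
      incomplete[[length(incomplete) + 1L]] <- ev
      next
    }
    eid <- eid + 1L
    ev$event_id <- eid
    ord <- order(ev$t_s_i, ev$id)
    ev$turning_rank <- integer(nrow(ev))
    ev$turning_rank[ord] <- seq_len(nrow(ev))
    ev$t_s <- min(ev$t_s_i)
    ev$t_e <- max(ev$t_e_i)
    events[[eid]] <- ev
  }
  out <- if (length(events)) {
    dplyr::bind_rows(events)[, names(empty)]
  } else {
    empty
  }
  structure(out, class = c("uturn_events", class(empty)),
            incomplete = if (length(incomplete)) {
              dplyr::bind_rows(incomplete)
            } else {
              empty[0, 1:8]
            })
}

#' Collective U-turn bounds from per-fish individual turns
#'
#' The collective start is the earliest individual start and the collective
#' end the latest individual end.
#'
#' @param events tibble with columns `t_s_i` and `t_e_i` (one row per
#'   fish), e.g. one event's rows from [detect_uturns()].
#' @return one-row tibble `t_s, t_e`.
#' @export
collective_uturn <- function(events) {
  if (nrow(events) == 0 || anyNA(events$t_s_i) || anyNA(events$t_e_i)) {
    stop("every fish needs a matched individual U-turn", call. = FALSE)
  }
  tibble::tibble(t_s = min(events$t_s_i), t_e = max(events$t_e_i))
}

#' Normalized event time
#'
#' Maps clock time onto the collective U-turn: 0 at the start, 1 at the
#' end, -1 one full duration before the start.
#'
#' @param t time (s), vectorized.
#' @param t_s,t_e collective start and end times (s), `t_e > t_s`.
#' @return numeric vector `(t - t_s) / (t_e - t_s)`.
#' @export
normalized_time <- function(t, t_s, t_e) {
  if (t_e <= t_s) stop("zero or negative U-turn duration", call. = FALSE)
  (t - t_s) / (t_e - t_s)
}

#' Position rank along the group direction of motion
#'
#' Projects each fish's position on the unit mean group velocity; rank 1 is
#' the most advanced fish. Frames where the mean velocity norm is below
#' `tol` get `NA` ranks. Ties break by ascending fish id.
#'
#' @param kin a `kinematics` tibble.
#' @param tol minimum group-velocity norm (mm/s) for a defined rank.
#' @return tibble `frame, time, id, position_rank`.
#' @export
position_rank <- function(kin, tol = 1e-8) {
  df <- tibble::as_tibble(kin)
  out <- df |>
    dplyr::group_by(.data$frame, .data$time) |>
    dplyr::mutate(
      zx = mean(.data$vx), zy = mean(.data$vy),
      nz = sqrt(.data$zx^2 + .data$zy^2),
      proj = (.data$x * .data$zx + .data$y * .data$zy) / .data$nz,
      position_rank = dplyr::if_else(
        is.finite(.data$nz) & .data$nz >= tol,
        order(order(-.data$proj, .data$id)), NA_integer_)) |>
    dplyr::ungroup()
  out[, c("frame", "time", "id", "position_rank")]
}

#' Distance rank of neighbors around each focal fish
#'
#' Adds `distance_rank` to a pair-geometry table: per focal fish and frame,
#' rank 1 is the nearest neighbor; ties break by ascending neighbor id.
#'
#' @param pairs tibble from [pair_geometry()].
#' @return `pairs` with a `distance_rank` column.
#' @export
distance_rank <- function(pairs) {
  pairs |>
    dplyr::group_by(.data$frame, .data$focal) |>
    dplyr::mutate(distance_rank = order(order(.data$d, .data$neighbor))) |>
    dplyr::ungroup()
}

#' Turning rank within one collective U-turn
#'
#' Rank 1 is the fish that starts its individual U-turn first; ties break
#' by ascending fish id.
#'
#' @param t_s_i numeric vector of individual start times.
#' @param id fish ids (defaults to the element order).
#' @return integer vector of ranks aligned with the input.
#' @export
turning_rank <- function(t_s_i, id = seq_along(t_s_i)) {
  stopifnot(!anyNA(t_s_i))
  ord <- order(t_s_i, id)
  rk <- integer(length(t_s_i)); rk[ord] <- seq_along(t_s_i)
  rk
}

#' @export
print.uturn_events <- function(x, ...) {
  n_ev <- length(unique(x$event_id))
  cat(sprintf("<uturn_events> %d collective U-turn(s), %d fish rows\n",
              n_ev, nrow(x)))
  NextMethod()
}

#' Broom-style tidiers for detected U-turn events
#'
#' `tidy()` returns the per-fish rows; `glance()` one row per event with
#' the collective bounds, duration and direction.
#'
#' @param x an `uturn_events` object from [detect_uturns()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.uturn_events <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.uturn_events
#' @export
glance.uturn_events <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(
      n_fish = dplyr::n(),
      t_s = .data$t_s[1], t_e = .data$t_e[1],
      duration = .data$t_e[1] - .data$t_s[1],
      direction_before = .data$direction_before[1],
      direction_after = .data$direction_after[1],
      .groups = "drop")
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
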