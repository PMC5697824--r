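#' Ring-tank geometry
#'
#' Describes the annular arena: an outer circular wall and an inner wall,
#' both centered on the same point. Defaults follow a 70 cm ring tank with a
#' 35 cm outer and 25 cm inner radius.
#'
#' @param center numeric length-2, tank center in mm.
#' @param outer_radius outer wall radius in mm.
#' @param inner_radius inner wall radius in mm.
#' @return an object of class `ring_geometry`.
#' @examples
#' ring_geometry()
#' @export
ring_geometry <- function(center = c(0, 0), outer_radius = 350, inner_radius = 250) {
  stopifnot(length(center) == 2, is.numeric(center),
            is.numeric(outer_radius), is.numeric(inner_radius))
  if (!(outer_radius > inner_radius && inner_radius > 0)) {
    stop("ring_geometry requires outer_radius > inner_radius > 0", call. = FALSE)
  }
  structure(
    list(center = as.numeric(center),
         outer_radius = as.numeric(outer_radius),
         inner_radius = as.numeric(inner_radius)),
    class = "ring_geometry"
  )
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf("<ring_geometry> center (%g, %g) mm, radii %g / %g mm\n",
              x$center[1], x$center[2], x$inner_radius, x$outer_radius))
  invisible(x)
}

new_trajectory_set <- function(df, geometry, dt) {
  df <- dplyr::arrange(df, .data$id, .data$time)
  structure(df,
            class = c("trajectory_set", class(tibble::tibble())),
            geometry = geometry, dt = dt)
}

#' Trajectory-set accessors
#'
#' A trajectory set is a tibble with one row per fish per frame (columns
#' `frame`, `time`, `id`, `x`, `y`, `valid`) carrying the tank geometry and
#' the frame interval `dt` as attributes, which these helpers read back.
#'
#' @param ts a `trajectory_set`.
#' @return `traj_geometry()` the `ring_geometry`; `traj_dt()` the frame
#'   interval in seconds.
#' @export
traj_geometry <- function(ts) attr(ts, "geometry")

#' @rdname traj_geometry
#' @export
traj_dt <- function(ts) attr(ts, "dt")

# keep attributes through dplyr verbs that rebuild the tibble
#' @export
`[.trajectory_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) restore_ts_attrs(out, x) else out
}

restore_ts_attrs <- function(out, template) {
  attr(out, "geometry") <- attr(template, "geometry")
  attr(out, "dt") <- attr(template, "dt")
  if (!inherits(out, "trajectory_set")) {
    class(out) <- c("trajectory_set", class(out))
  }
  out
}

#' Build a trajectory set from a per-frame table
#'
#' @param df data frame with columns `frame`, `time`, `id`, `x`, `y` and
#'   optionally `valid` (logical). Missing positions may be encoded as `NA`
#'   in `x`/`y`; such rows get `valid = FALSE`.
#' @param geometry a [ring_geometry()].
#' @param dt frame interval in seconds; inferred from `time` when `NULL`.
#' @param tol relative tolerance on time-step uniformity.
#' @return a `trajectory_set` tibble.
#' @export
as_trajectory_set <- function(df, geometry, dt = NULL, tol = 1e-6) {
  stopifnot(inherits(geometry, "ring_geometry"))
  need <- c("frame", "time", "id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("trajectory table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (!"valid" %in% names(df)) df$valid <- TRUE
  df$valid <- df$valid & is.finite(df$x) & is.finite(df$y)
  df$id <- as.character(df$id)
  if (anyDuplicated(df[, c("time", "id")])) {
    stop("duplicate (time, id) rows in trajectory data", call. = FALSE)
  }
  df <- dplyr::arrange(df, .data$id, .data$time)
  times <- sort(unique(df$time))
  if (length(times) < 2) stop("need at least two frames", call. = FALSE)
  steps <- diff(times)
  dt_obs <- stats::median(steps)
  if (any(abs(steps - dt_obs) > tol * max(dt_obs, 1e-12))) {
    stop("non-uniform time step in trajectory data (observed steps vary ",
         "beyond tolerance)", call. = FALSE)
  }
  if (is.null(dt)) dt <- dt_obs
  # every fish must sit on the common clock
  per_id <- dplyr::count(df, .data$id)
  if (length(unique(per_id$n)) != 1 || per_id$n[1] != length(times)) {
    stop("all fish must share an identical time base", call. = FALSE)
  }
  new_trajectory_set(df[, c("frame", "time", "id", "x", "y", "valid")],
                     geometry, dt)
}

#' Read trajectories from delimited text
#'
#' Reads a CSV or TSV file (dialect autodetected from the header line) with
#' columns `frame`, `time`, `id`, `x`, `y` and optionally `orientation`.
#' Blank or `NaN` positions are recorded as invalid frames. Positions may be
#' stored in mm (default) or m; metres are converted on read.
#'
#' @param path file path.
#' @param geometry a [ring_geometry()] (always in mm).
#' @param units `"mm"` or `"m"` for the x/y columns.
#' @return a `trajectory_set` tibble.
#' @export
read_trajectories <- function(path, geometry, units = c("mm", "m")) {
  units <- match.arg(units)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, na = c("", "NA", "NaN"))
  if (units == "m") {
    df$x <- df$x * 1000
    df$y <- df$y * 1000
  }
  as_trajectory_set(df, geometry)
}

#' Write trajectories to delimited text
#'
#' Inverse of [read_trajectories()]: invalid frames are written with blank
#' positions so a read-back reproduces the valid mask.
#'
#' @param ts a `trajectory_set`.
#' @param path output file path (`.tsv` extension selects tab delimiting).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ts, path) {
  out <- tibble::as_tibble(ts)
  out$x[!out$valid] <- NA_real_
  out$y[!out$valid] <- NA_real_
  out$valid <- NULL
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Interpolate short tracking gaps
#'
#' Linearly fills every interior run of at most `max_gap` consecutive
#' invalid frames that is bounded by valid frames on both sides, in x and y
#' independently. Longer runs and runs touching the start or end of the
#' record are left invalid and listed in the gap report (attribute
#' `"gap_report"`, also returned by [gap_report()]).
#'
#' @param ts a `trajectory_set`.
#' @param max_gap longest run length (frames) that is filled; default 50.
#' @return a `trajectory_set` with gaps filled and a gap report attached.
#' @export
interpolate_gaps <- function(ts, max_gap = 50) {
  stopifnot(max_gap >= 0)
  df <- tibble::as_tibble(ts)
  report <- list()
  pieces <- lapply(split(df, df$id), function(tr) {
    tr <- tr[order(tr$time), ]
    r <- rle(!tr$valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (g in which(r$values)) {
      i0 <- starts[g]; i1 <- ends[g]; len <- r$lengths[g]
      interior <- i0 > 1L && i1 < nrow(tr)
      if (interior && len <= max_gap) {
        idx <- (i0 - 1L):(i1 + 1L)
        tr$x[idx] <- stats::approx(tr$time[c(i0 - 1L, i1 + 1L)],
                                   tr$x[c(i0 - 1L, i1 + 1L)],
                                   xout = tr$time[idx])$y
        tr$y[idx] <- stats::approx(tr$time[c(i0 - 1L, i1 + 1L)],
                                   tr$y[c(i0 - 1L, i1 + 1L)],
                                   xout = tr$time[idx])$y
        tr$valid[i0:i1] <- TRUE
        action <- "interpolated"
      } else {
        action <- if (interior) "too_long" else "boundary"
      }
      report[[length(report) + 1L]] <<- tibble::tibble(
        fish_id = tr$id[1], start_frame = tr$frame[i0],
        length = len, action = action)
    }
    tr
  })
  out <- dplyr::bind_rows(pieces)
  out <- new_trajectory_set(out, traj_geometry(ts), traj_dt(ts))
  attr(out, "gap_report") <- if (length(report)) {
    dplyr::bind_rows(report)
  } else {
    tibble::tibble(fish_id = character(), start_frame = numeric(),
                   length = integer(), action = character())
  }
  out
}

#' @rdname interpolate_gaps
#' @export
gap_report <- function(ts) {
  rep <- attr(ts, "gap_report")
  if (is.null(rep)) {
    tibble::tibble(fish_id = character(), start_frame = numeric(),
                   length = integer(), action = character())
  } else {
    rep
  }
}

#' Convert positions to polar coordinates about the tank center
#'
#' Adds `rho` (distance from center, mm) and `psi` (angular position from
#' the horizontal, anticlockwise positive, wrapped to (-pi, pi]) per fish
#' per frame.
#'
#' @param ts a `trajectory_set`.
#' @return a tibble `frame, time, id, rho, psi, valid`.
#' @export
to_polar <- function(ts) {
  g <- traj_geometry(ts)
  df <- tibble::as_tibble(ts)
  dx <- df$x - g$center[1]
  dy <- df$y - g$center[2]
  rho <- sqrt(dx^2 + dy^2)
  if (any(df$valid & rho == 0)) {
    stop("position exactly at tank center: angular position undefined",
         call. = FALSE)
  }
  tibble::tibble(frame = df$frame, time = df$time, id = df$id,
                 rho = rho, psi = wrap_angle(atan2(dy, dx)),
                 valid = df$valid)
}

#' Rebuild Cartesian positions from polar tracks
#'
#' Inverse of [to_polar()]; used by the null-model machinery after rotating
#' or mirroring tracks in polar form.
#'
#' @param polar tibble with `frame, time, id, rho, psi, valid`.
#' @param geometry a [ring_geometry()].
#' @param dt frame interval (s).
#' @return a `trajectory_set`.
#' @export
from_polar <- function(polar, geometry, dt) {
  df <- tibble::tibble(
    frame = polar$frame, time = polar$time, id = polar$id,
    x = geometry$center[1] + polar$rho * cos(polar$psi),
    y = geometry$center[2] + polar$rho * sin(polar$psi),
    valid = polar$valid)
  new_trajectory_set(df, geometry, dt)
}
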