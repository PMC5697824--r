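#' Rank and count histograms of influential neighbors
#'
#' The four per-event-pooled histograms characterizing where influential
#' neighbors sit in the group: (a) proportion of focal-fish-frames by the
#' number of influential neighbors `N_if` in `0..n_fish-1`; (b) proportion
#' of influence records by the influential neighbor's distance rank; (c) by
#' its position rank; (d) by its turning rank. Proportions are of time
#' spent *inside* the collective U-turn (`span = "turn"`, the default);
#' `span = "window"` pools the whole analysis window instead. Each block
#' is normalized to sum to 1 (an all-zero block carries `empty = TRUE`).
#'
#' @param analyses a list of `uturn_analysis` objects ([analyze_uturn()]),
#'   or a single one.
#' @param n_fish group size (defines the bin ranges).
#' @param span `"turn"` (frames with normalized time in `[0, 1]`) or
#'   `"window"` (all analyzed frames).
#' @return tibble `block, value, count, proportion, empty` with blocks
#'   `"n_if"`, `"distance_rank"`, `"position_rank"`, `"turning_rank"`.
#' @export
rank_histograms <- function(analyses, n_fish = 5,
                            span = c("turn", "window")) {
  span <- match.arg(span)
  if (inherits(analyses, "uturn_analysis")) analyses <- list(analyses)
  nif_counts <- integer(n_fish)            # N_if in 0..n_fish-1
  dist_counts <- integer(n_fish - 1)       # rank 1..n_fish-1
  pos_counts <- integer(n_fish)            # rank 1..n_fish
  turn_counts <- integer(n_fish)           # rank 1..n_fish
  for (an in analyses) {
    nif <- an$nif
    rec <- tibble::as_tibble(an$records)
    if (span == "turn" && nrow(an$events) > 0) {
      nif <- nif[!is.na(nif$t_bar) & nif$t_bar >= 0 & nif$t_bar <= 1, ]
      ev1 <- tibble::as_tibble(an$events)
      rec <- rec[rec$time >= ev1$t_s[1] & rec$time <= ev1$t_e[1], ]
    }
    tab <- table(factor(nif$n_if, levels = 0:(n_fish - 1)))
    nif_counts <- nif_counts + as.integer(tab)
    if (nrow(rec) == 0) next
    # ranks are combo-independent; reuse them when the analysis carries
    # precomputed copies (parameter sweeps)
    dr <- an$dranks %||% distance_rank(an$pairs)
    dr <- dr[, c("frame", "focal", "neighbor", "distance_rank")]
    pr <- an$pranks %||% position_rank(an$kin)
    pr <- pr[, c("frame", "id", "position_rank")]
    ev <- tibble::as_tibble(an$events)[, c("id", "turning_rank")]
    rec2 <- rec |>
      dplyr::left_join(dr, by = c("frame", "focal", "neighbor")) |>
      dplyr::left_join(pr, by = c("frame", "neighbor" = "id")) |>
      dplyr::left_join(ev, by = c("neighbor" = "id"))
    tabd <- table(factor(rec2$distance_rank, levels = 1:(n_fish - 1)))
    tabp <- table(factor(rec2$position_rank, levels = 1:n_fish))
    tabt <- table(factor(rec2$turning_rank, levels = 1:n_fish))
    dist_counts <- dist_counts + as.integer(tabd)
    pos_counts <- pos_counts + as.integer(tabp)
    turn_counts <- turn_counts + as.integer(tabt)
  }
  block <- function(name, values, counts) {
    tot <- sum(counts)
    tibble::tibble(block = name, value = values, count = counts,
                   proportion = if (tot > 0) counts / tot else 0,
                   empty = tot == 0)
  }
  dplyr::bind_rows(
    block("n_if", 0:(n_fish - 1), nif_counts),
    block("distance_rank", 1:(n_fish - 1), dist_counts),
    block("position_rank", 1:n_fish, pos_counts),
    block("turning_rank", 1:n_fish, turn_counts))
}

#' Normalized-time courses of speed, polarization, N and eta
#'
#' Resamples each event's per-fish series of speed, group polarization,
#' number of influential neighbors and its relative variation onto a
#' common normalized-time grid over `[-1, 2]` (linear interpolation,
#' default step 0.05) and averages across fish and events. `eta` averages
#' only over frames where it is defined.
#'
#' @inheritParams rank_histograms
#' @param step grid step in normalized time.
#' @return a `time_course` tibble `t_bar, V, P, N, eta, n_V, n_P, n_N,
#'   n_eta` (per-point sample counts).
#' @export
time_course <- function(analyses, step = 0.05) {
  if (inherits(analyses, "uturn_analysis")) analyses <- list(analyses)
  grid <- seq(-1, 2, by = step)
  acc <- tibble::tibble(t_bar = grid, V = 0, P = 0, N = 0, eta = 0,
                        n_V = 0L, n_P = 0L, n_N = 0L, n_eta = 0L)
  for (an in analyses) {
    if (nrow(an$events) == 0) next
    ev1 <- dplyr::filter(tibble::as_tibble(an$events),
                         .data$event_id == min(.data$event_id))
    t_s <- ev1$t_s[1]; t_e <- ev1$t_e[1]
    kin <- tibble::as_tibble(an$kin)
    kin$t_bar <- normalized_time(kin$time, t_s, t_e)
    pol <- polarization_series(an$kin)
    pol$t_bar <- normalized_time(pol$time, t_s, t_e)
    # per-fish speed resampled then averaged across fish
    for (f in unique(kin$id)) {
      tr <- kin[kin$id == f, ]
      acc <- add_resampled(acc, grid, tr$t_bar, tr$speed, "V")
    }
    acc <- add_resampled(acc, grid, pol$t_bar, pol$polarization, "P")
    nif <- an$nif
    for (f in unique(nif$id)) {
      tr <- nif[nif$id == f, ]
      acc <- add_resampled(acc, grid, tr$t_bar, tr$n_if, "N")
      acc <- add_resampled(acc, grid, tr$t_bar, tr$eta, "eta")
    }
  }
  out <- acc |>
    dplyr::mutate(V = ifelse(.data$n_V > 0, .data$V / .data$n_V, NA_real_),
                  P = ifelse(.data$n_P > 0, .data$P / .data$n_P, NA_real_),
                  N = ifelse(.data$n_N > 0, .data$N / .data$n_N, NA_real_),
                  eta = ifelse(.data$n_eta > 0, .data$eta / .data$n_eta,
                               NA_real_))
  class(out) <- c("time_course", class(out))
  out
}

# linear interpolation of one series onto the grid; accumulate sums/counts
add_resampled <- function(acc, grid, t_bar, y, col) {
  ok <- !is.na(t_bar) & !is.na(y)
  if (sum(ok) < 2) return(acc)
  res <- stats::approx(t_bar[ok], y[ok], xout = grid, rule = 1)$y
  has <- !is.na(res)
  acc[[col]][has] <- acc[[col]][has] + res[has]
  acc[[paste0("n_", col)]][has] <- acc[[paste0("n_", col)]][has] + 1L
  acc
}

#' Spatial map of influential neighbors in the focal frame
#'
#' Rotates each influence record's neighbor position into the focal fish's
#' frame (focal at the origin, heading along +y, so "ahead" is up) and
#' accumulates per-cell occupancy and mean relative velocity on a square
#' grid, plus a polar histogram over (viewing angle, distance) bins.
#'
#' @param records an `influence_records` tibble.
#' @param pairs the matching [pair_geometry()] tibble.
#' @param cell square cell side in mm (default 20).
#' @param angle_bin polar angular bin width in degrees (default 30).
#' @param radius_bin polar radial bin width in mm (default 20).
#' @param max_radius largest distance kept in the polar histogram.
#' @return a `spatial_map` list: `cells` (tibble `cx, cy, count, mean_dvx,
#'   mean_dvy`), `polar` (tibble `angle_lo, angle_hi, r_lo, r_hi, count`),
#'   `n_records`.
#' @export
spatial_map <- function(records, pairs, cell = 20, angle_bin = 30,
                        radius_bin = 20, max_radius = 200) {
  rec <- tibble::as_tibble(records) |>
    dplyr::inner_join(tibble::as_tibble(pairs),
                      by = c("frame", "focal", "neighbor"),
                      suffix = c("", ".p"))
  # focal frame: rotate so the focal heading points along +y
  phii <- atan2(rec$uy, rec$ux) - rec$theta_view # focal heading angle
  rot <- pi / 2 - phii
  rx <- rec$ux * cos(rot) - rec$uy * sin(rot)
  ry <- rec$ux * sin(rot) + rec$uy * cos(rot)
  rvx <- rec$dvx * cos(rot) - rec$dvy * sin(rot)
  rvy <- rec$dvx * sin(rot) + rec$dvy * cos(rot)
  cells <- tibble::tibble(
    cx = floor(rx / cell) * cell + cell / 2,
    cy = floor(ry / cell) * cell + cell / 2,
    dvx = rvx, dvy = rvy) |>
    dplyr::group_by(.data$cx, .data$cy) |>
    dplyr::summarise(count = dplyr::n(), mean_dvx = mean(.data$dvx),
                     mean_dvy = mean(.data$dvy), .groups = "drop")
  ang_deg <- (rec$theta_view * 180 / pi) %% 360
  a_lo <- floor(ang_deg / angle_bin) * angle_bin
  r_lo <- pmin(floor(rec$d / radius_bin) * radius_bin, max_radius)
  polar <- tibble::tibble(angle_lo = a_lo, r_lo = r_lo) |>
    dplyr::count(.data$angle_lo, .data$r_lo, name = "count") |>
    dplyr::mutate(angle_hi = .data$angle_lo + angle_bin,
                  r_hi = .data$r_lo + radius_bin)
  structure(list(cells = cells, polar = polar, n_records = nrow(rec),
                 cell = cell),
            class = "spatial_map")
}

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("<spatial_map> %d records over %d cells (%g mm)\n",
              x$n_records, nrow(x$cells), x$cell))
  invisible(x)
}

#' Distance and viewing-angle distributions, influential vs all pairs
#'
#' Histograms of the focal-neighbor distance `d_ij` and viewing angle
#' `theta_ij` for (i) influential pairs and (ii) all pairs, with means and
#' standard deviations, to compare where influential neighbors sit against
#' the background geometry of the group.
#'
#' @inheritParams spatial_map
#' @param d_bin distance bin width (mm).
#' @param angle_bin angle bin width (degrees).
#' @return list with `histograms` (tibble `variable, set, bin_lo, bin_hi,
#'   count, proportion`) and `summary` (tibble `variable, set, mean, sd,
#'   n`).
#' @export
angle_distance_distributions <- function(records, pairs, d_bin = 10,
                                         angle_bin = 10) {
  rec <- tibble::as_tibble(records) |>
    dplyr::inner_join(tibble::as_tibble(pairs),
                      by = c("frame", "focal", "neighbor"),
                      suffix = c("", ".p"))
  sets <- list(influential = rec,
               all_pairs = tibble::as_tibble(pairs))
  hist_of <- function(x, width) {
    lo <- floor(x / width) * width
    tibble::tibble(bin_lo = lo) |>
      dplyr::count(.data$bin_lo, name = "count") |>
      dplyr::mutate(bin_hi = .data$bin_lo + width,
                    proportion = .data$count / sum(.data$count))
  }
  hs <- purrr::imap(sets, function(df, nm) {
    dplyr::bind_rows(
      dplyr::mutate(hist_of(df$d, d_bin), variable = "d", set = nm),
      dplyr::mutate(hist_of(df$theta_view * 180 / pi, angle_bin),
                    variable = "theta", set = nm))
  })
  sm <- purrr::imap(sets, function(df, nm) {
    tibble::tibble(
      variable = c("d", "theta"), set = nm,
      mean = c(mean(df$d), mean(df$theta_view * 180 / pi, na.rm = TRUE)),
      sd = c(if (nrow(df) > 1) sd(df$d) else 0,
             if (nrow(df) > 1) sd(df$theta_view * 180 / pi, na.rm = TRUE)
             else 0),
      n = nrow(df))
  })
  list(histograms = dplyr::bind_rows(hs), summary = dplyr::bind_rows(sm))
}

#' Mean time-delay over (heading difference, distance) bins
#'
#' Averages the extracted delay of influence records on a 2D grid of
#' heading difference and separation distance. Empty bins are absent from
#' the output (missing, never zero).
#'
#' @inheritParams spatial_map
#' @param phi_bin heading-difference bin width in degrees (default 20).
#' @param d_bin distance bin width in mm (default 20).
#' @return tibble `phi_lo, phi_hi, d_lo, d_hi, mean_tau, count`.
#' @export
delay_map <- function(records, pairs, phi_bin = 20, d_bin = 20) {
  rec <- tibble::as_tibble(records) |>
    dplyr::inner_join(tibble::as_tibble(pairs),
                      by = c("frame", "focal", "neighbor"),
                      suffix = c("", ".p"))
  phi_deg <- abs(rec$phi_diff) * 180 / pi
  rec |>
    dplyr::mutate(phi_lo = floor(phi_deg / phi_bin) * phi_bin,
                  d_lo = floor(.data$d / d_bin) * d_bin) |>
    dplyr::group_by(.data$phi_lo, .data$d_lo) |>
    dplyr::summarise(mean_tau = mean(.data$tau), count = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(phi_hi = .data$phi_lo + phi_bin,
                  d_hi = .data$d_lo + d_bin)
}
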