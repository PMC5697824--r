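#' Analysis configuration for influential-neighbor identification
#'
#' Bundles the parameters of the delay-extraction and identification stage:
#' the correlation half-window `w` (the windowed correlation averages over
#' `2w + 1` frames), the correlation threshold `c_min`, the
#' multi-influencer tolerance `eps` (percent of the top passing score), the
#' reaction-time floor `tau_r` in seconds (candidates at shorter delays are
#' discarded as faster than any plausible sensorimotor response), the
#' initial delay bound `tau0` of the recursion, and a hard cap `tau_max` on
#' the delay grid in frames.
#'
#' @param w half-window in frames (>= 0); default 2.
#' @param c_min correlation threshold in `[-1, 1]`; default 0.95.
#' @param eps percent-of-maximum tolerance (>= 0); default 3.
#' @param tau_r reaction-time floor in seconds; default 0.04.
#' @param tau0 initial delay bound in frames; default 50.
#' @param tau_max largest delay (frames) ever considered; default 100
#'   (2 s at 50 Hz, the span over which pair correlations are inspected).
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(w = 2, c_min = 0.95, eps = 3, tau_r = 0.04,
                            tau0 = 50, tau_max = 100) {
  stopifnot(w >= 0, c_min >= -1, c_min <= 1, eps >= 0, tau_r >= 0,
            tau0 >= 0, tau_max >= tau0)
  structure(list(w = as.integer(w), c_min = c_min, eps = eps, tau_r = tau_r,
                 tau0 = as.integer(tau0), tau_max = as.integer(tau_max)),
            class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf(
    "<analysis_config> w=%d frames, c_min=%g, eps=%g%%, tau_r=%g s, tau0=%d, tau_max=%d\n",
    x$w, x$c_min, x$eps, x$tau_r, x$tau0, x$tau_max))
  invisible(x)
}

#' Directional correlation of two headings
#'
#' The dot product of the unit heading vectors, i.e. the cosine of the
#' heading difference: 1 for identical directions, -1 for opposite, 0 for
#' perpendicular. Vectorized; `NA` headings propagate.
#'
#' @param phi_i heading(s) of the focal fish at time t (rad).
#' @param phi_j heading(s) of the neighbor at time t - tau (rad).
#' @return numeric in `[-1, 1]`.
#' @examples
#' directional_correlation(0, pi / 2) # 0
#' @export
directional_correlation <- function(phi_i, phi_j) cos(phi_i - phi_j)

# aligned heading series for one ordered pair, NA where undefined
pair_headings <- function(kin, focal, neighbor) {
  df <- tibble::as_tibble(kin)
  fi <- df[df$id == focal, ]
  fj <- df[df$id == neighbor, ]
  fi <- fi[order(fi$time), ]
  fj <- fj[order(fj$time), ]
  if (nrow(fi) != nrow(fj) || any(fi$time != fj$time)) {
    stop("focal and neighbor are not on a common clock", call. = FALSE)
  }
  pi_ <- fi$phi; pj <- fj$phi
  pi_[!fi$valid] <- NA_real_
  pj[!fj$valid] <- NA_real_
  list(time = fi$time, frame = fi$frame, phi_i = pi_, phi_j = pj)
}

#' Windowed directional correlation field
#'
#' `C(t, tau, w)` is the mean of the directional correlation
#' `H(t + k dt, tau)` over `k = -w..w`. Cells needing history before the
#' start of the record (or any undefined heading in the window) are `NA`;
#' they are masked, never zero-filled.
#'
#' @param kin a `kinematics` tibble.
#' @param focal,neighbor fish ids (ordered pair: focal at `t`, neighbor at
#'   `t - tau`).
#' @param w half-window in frames.
#' @param tau_max largest delay in frames.
#' @return a list with `C` (matrix, rows = frames, cols = delays
#'   `0..tau_max`), `H` (same layout), `time`, `frame`.
#' @export
correlation_field <- function(kin, focal, neighbor, w = 2, tau_max = 100) {
  ph <- pair_headings(kin, focal, neighbor)
  M <- length(ph$phi_i)
  if (M < 2 * w + 1) {
    stop("record shorter than the correlation window (2w + 1 frames)",
         call. = FALSE)
  }
  taus <- 0:tau_max
  H <- matrix(NA_real_, nrow = M, ncol = length(taus))
  for (tau in taus) {
    if (tau >= M) break
    idx <- (tau + 1):M
    H[idx, tau + 1] <- cos(ph$phi_i[idx] - ph$phi_j[idx - tau])
  }
  C <- if (w == 0) {
    H
  } else {
    apply(H, 2, function(col) {
      as.numeric(stats::filter(col, rep(1 / (2 * w + 1), 2 * w + 1),
                               sides = 2))
    })
  }
  list(C = C, H = H, time = ph$time, frame = ph$frame,
       w = w, tau_max = tau_max, focal = focal, neighbor = neighbor)
}

#' Windowed correlation at a single (t, tau)
#'
#' Convenience scalar form of [correlation_field()]: the mean of `H` over
#' the `2w + 1` frames centered on `t`. Returns `NA` when any term is
#' unavailable.
#'
#' @inheritParams correlation_field
#' @param t time (s) at which to evaluate.
#' @param tau delay in frames.
#' @return scalar correlation or `NA`.
#' @export
windowed_correlation <- function(kin, focal, neighbor, t, tau, w = 2) {
  ph <- pair_headings(kin, focal, neighbor)
  k <- which.min(abs(ph$time - t))
  M <- length(ph$phi_i)
  ks <- (k - w):(k + w)
  if (any(ks < 1) || any(ks > M) || any(ks - tau < 1)) return(NA_real_)
  mean(cos(ph$phi_i[ks] - ph$phi_j[ks - tau]))
}

#' Recursive per-frame delay extraction for one ordered pair
#'
#' At each frame `k` the delay `tau*_k` is the smallest delay maximizing
#' the windowed correlation over the search range `[0, tau*_{k-1} + 1]`
#' (capped at `tau_max`): once a fish has been found to copy its neighbor's
#' past heading at lag `tau`, it is never assumed to reach further back
#' than one frame more per elapsed frame. The recursion activates at the
#' first frame whose history covers the entire initial search range
#' `[0, tau0 + 1]` (capped at `tau_max`): starting earlier would pin the
#' tracker at whatever small delay happens to be available, and the
#' one-frame-per-frame growth bound could never carry it across a dip in
#' the correlation profile. Frames before activation, and frames where a
#' heading is undefined, yield `NA` and leave the search range unchanged.
#'
#' @param kin a `kinematics` tibble.
#' @param focal,neighbor fish ids.
#' @param config an [analysis_config()].
#' @param field optional precomputed [correlation_field()] (must match
#'   `config$w`); avoids recomputation in sweeps.
#' @return a `delay_track` tibble `focal, neighbor, frame, time, tau_star`
#'   (frames), `gamma` (the correlation at `tau_star`).
#' @export
extract_delays <- function(kin, focal, neighbor, config = analysis_config(),
                           field = NULL) {
  if (is.null(field)) {
    field <- correlation_field(kin, focal, neighbor,
                               w = config$w, tau_max = config$tau_max)
  }
  C <- field$C
  M <- nrow(C)
  tau_star <- rep(NA_integer_, M)
  gamma <- rep(NA_real_, M)
  tau_prev <- config$tau0
  hi0 <- min(config$tau0 + 1L, config$tau_max)
  # activation: full initial range must have history (and a full window)
  k_start <- hi0 + config$w + 2L
  if (k_start > M) return(delay_track_tibble(focal, neighbor, field,
                                             tau_star, gamma))
  for (k in k_start:M) {
    hi <- min(tau_prev + 1L, config$tau_max)
    cand <- C[k, 1:(hi + 1L)]
    ok <- which(!is.na(cand))
    if (length(ok)) {
      best <- ok[which.max(cand[ok])] # first max = smallest tau on ties
      tau_star[k] <- best - 1L
      gamma[k] <- cand[best]
      tau_prev <- tau_star[k]
    }
  }
  delay_track_tibble(focal, neighbor, field, tau_star, gamma)
}

delay_track_tibble <- function(focal, neighbor, field, tau_star, gamma) {
  out <- tibble::tibble(focal = focal, neighbor = neighbor,
                        frame = field$frame, time = field$time,
                        tau_star = tau_star, gamma = gamma)
  class(out) <- c("delay_track", class(out))
  out
}

#' Delay tracks for every ordered pair in the group
#'
#' @inheritParams extract_delays
#' @return row-bound `delay_track` tibble over all ordered pairs.
#' @export
extract_all_delays <- function(kin, config = analysis_config()) {
  ids <- sort(unique(tibble::as_tibble(kin)$id))
  pairs <- expand.grid(focal = ids, neighbor = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$focal != pairs$neighbor, ]
  out <- purrr::pmap(pairs, function(focal, neighbor) {
    extract_delays(kin, focal, neighbor, config)
  })
  dplyr::bind_rows(out)
}

#' Identify influential neighbors frame by frame
#'
#' A neighbor `j` of focal `i` at frame `k` is a candidate when its delay
#' track is defined there; it passes the gates when its correlation
#' `gamma = C(t_k, tau*_k, w)` exceeds `c_min` and its delay exceeds the
#' reaction-time floor `tau_r`. Among passing candidates, all scoring
#' within `eps` percent of the best score are retained, so nearly-tied
#' neighbors count as simultaneous influencers.
#'
#' @param delays a `delay_track` tibble for all ordered pairs
#'   ([extract_all_delays()]).
#' @param config an [analysis_config()].
#' @param dt frame interval in seconds.
#' @return an `influence_records` tibble
#'   `time, frame, focal, neighbor, tau, tau_frames, C`, the edge list of
#'   the time-resolved influence network.
#' @export
identify_influential <- function(delays, config = analysis_config(),
                                 dt = 0.02) {
  gated <- tibble::as_tibble(delays) |>
    dplyr::filter(!is.na(.data$gamma),
                  .data$gamma > config$c_min,
                  .data$tau_star * dt > config$tau_r)
  if (nrow(gated) > 0) {
    gated <- gated |>
      dplyr::group_by(.data$focal, .data$frame) |>
      dplyr::filter(.data$gamma >=
                      (1 - config$eps / 100) * max(.data$gamma)) |>
      dplyr::ungroup()
  }
  rec <- gated |>
    dplyr::transmute(time = .data$time, frame = .data$frame,
                     focal = .data$focal, neighbor = .data$neighbor,
                     tau = .data$tau_star * dt,
                     tau_frames = .data$tau_star, C = .data$gamma)
  class(rec) <- c("influence_records", class(rec))
  attr(rec, "config") <- config
  rec
}

#' Count influential neighbors per fish per frame
#'
#' `N_if(i, t)` is the number of distinct influential neighbors of fish `i`
#' at frame `t`; frames (and fish) with no record count 0. The frame/fish
#' universe is taken from `kin` so absent records are explicit zeros.
#'
#' @param records an `influence_records` tibble.
#' @param kin a `kinematics` tibble defining the frame grid, or a tibble
#'   with columns `frame, time, id`.
#' @param frames optional numeric range `c(min, max)` restricting frames.
#' @return tibble `frame, time, id, n_if`.
#' @export
count_influential <- function(records, kin, frames = NULL) {
  grid <- tibble::as_tibble(kin)[, c("frame", "time", "id")]
  if (!is.null(frames)) {
    grid <- dplyr::filter(grid, .data$frame >= frames[1],
                          .data$frame <= frames[2])
  }
  counts <- tibble::as_tibble(records) |>
    dplyr::distinct(.data$frame, .data$focal, .data$neighbor) |>
    dplyr::count(.data$frame, id = .data$focal, name = "n_if")
  grid |>
    dplyr::left_join(counts, by = c("frame", "id")) |>
    dplyr::mutate(n_if = dplyr::coalesce(.data$n_if, 0L)) |>
    dplyr::arrange(.data$id, .data$frame)
}

#' Relative variation of the number of influential neighbors
#'
#' `eta(t) = |N_if(t + dt) - N_if(t)| / N_if(t)` per fish and frame.
#' Frames with `N_if(t) = 0` (zero denominator) or without a successor
#' frame are `NA` and are excluded from any averaging downstream.
#'
#' @param nif tibble from [count_influential()].
#' @return `nif` with an added `eta` column.
#' @export
eta_series <- function(nif) {
  nif |>
    dplyr::group_by(.data$id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(eta = dplyr::if_else(
      .data$n_if > 0,
      abs(dplyr::lead(.data$n_if) - .data$n_if) / .data$n_if,
      NA_real_)) |>
    dplyr::ungroup()
}

#' Remove chains of influence
#'
#' Correlation chains can masquerade as direct influence: if focal `F1` is
#' simultaneously influenced by `F2` and `F3` while `F2` is itself
#' influenced by `F3` at the same time, the edge `(F1, F2)` is dropped
#' (and symmetrically `(F1, F3)` when `F3` is influenced by `F2`).
#' Conditions are evaluated on the original record set, so mutual pairs
#' drop both edges. The number of removed records is attached as attribute
#' `"n_removed"`.
#'
#' @param records an `influence_records` tibble.
#' @return filtered `influence_records` tibble.
#' @export
remove_influence_chains <- function(records) {
  rec <- tibble::as_tibble(records)
  if (nrow(rec) == 0) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  # (f, n) drops when some other influencer m of f influences n at t:
  # edge (n <- m) present with m in influencers(f, t), m != n
  via <- rec |>
    dplyr::inner_join(
      dplyr::select(rec, frame2 = "frame", focal2 = "focal",
                    m = "neighbor"),
      by = c("frame" = "frame2", "neighbor" = "focal2"),
      relationship = "many-to-many") |>
    dplyr::filter(.data$m != .data$focal) |>
    dplyr::semi_join(
      dplyr::select(rec, "frame", "focal", m = "neighbor"),
      by = c("frame", "focal", "m")) |>
    dplyr::distinct(.data$frame, .data$focal, .data$neighbor)
  out <- dplyr::anti_join(rec, via, by = c("frame", "focal", "neighbor"))
  n_removed <- nrow(rec) - nrow(out)
  class(out) <- class(records)
  attr(out, "config") <- attr(records, "config")
  attr(out, "n_removed") <- n_removed
  out
}

#' Single global delay for one ordered pair
#'
#' The delay maximizing the time-averaged directional correlation over the
#' whole record (smallest delay on ties). A single-number summary in the
#' style of static leadership-network analyses; the per-frame recursion of
#' [extract_delays()] is the package's main instrument, and this global
#' delay is mainly useful to show how a single compromise value can
#' misrepresent datasets whose true delay changes over time.
#'
#' @inheritParams correlation_field
#' @return one-row tibble `focal, neighbor, tau_star` (frames),
#'   `mean_H` (the maximized average correlation).
#' @export
global_delay <- function(kin, focal, neighbor, tau_max = 100) {
  ph <- pair_headings(kin, focal, neighbor)
  M <- length(ph$phi_i)
  if (M < 2) stop("need at least 2 frames", call. = FALSE)
  taus <- 0:min(tau_max, M - 1)
  avg <- vapply(taus, function(tau) {
    idx <- (tau + 1):M
    h <- cos(ph$phi_i[idx] - ph$phi_j[idx - tau])
    if (all(is.na(h))) NA_real_ else mean(h, na.rm = TRUE)
  }, numeric(1))
  ok <- which(!is.na(avg))
  if (!length(ok)) stop("no delay with overlapping data", call. = FALSE)
  best <- ok[which.max(avg[ok])]
  tibble::tibble(focal = focal, neighbor = neighbor,
                 tau_star = taus[best], mean_H = avg[best])
}

#' @export
print.influence_records <- function(x, ...) {
  cat(sprintf("<influence_records> %d records, %d focal fish\n",
              nrow(x), length(unique(x$focal))))
  NextMethod()
}

#' Summaries of an influence-record set
#'
#' `glance()` gives one row of whole-set summaries: record count, number of
#' focal fish, mean/sd of delay and correlation.
#'
#' @param x an `influence_records` tibble.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.influence_records <- function(x, ...) {
  tibble::tibble(n_records = nrow(x),
                 n_focal = length(unique(x$focal)),
                 mean_tau = mean(x$tau), sd_tau = sd(x$tau),
                 mean_C = mean(x$C),
                 n_removed = attr(x, "n_removed") %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
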