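#' The standard parameter sweep grid
#'
#' The cartesian product of `w` in 0..4, `eps` in \{3, 5\} and `c_min` in
#' \{0.995, 0.99, 0.95, 0.5\}: 40 combinations, ordered lexicographically
#' by (eps, c_min, w).
#'
#' @return tibble `combo, eps, c_min, w` with 40 rows.
#' @export
sweep_grid <- function() {
  g <- expand.grid(w = 0:4, c_min = c(0.995, 0.99, 0.95, 0.5),
                   eps = c(3, 5))
  g <- g[order(g$eps, g$c_min, g$w), c("eps", "c_min", "w")]
  tibble::tibble(combo = seq_len(nrow(g)), eps = g$eps, c_min = g$c_min,
                 w = g$w)
}

#' 19-dimensional summary vector of one analysis run
#'
#' Concatenates the four rank-histogram blocks in the order: 5 proportions
#' of the number of influential neighbors (`N_if` 0..4), 4 proportions of
#' distance rank, 5 of position rank, 5 of turning rank. Blocks with no
#' data are all-zero and flagged in the `"empty_blocks"` attribute.
#'
#' @param hists tibble from [rank_histograms()] (with `n_fish = 5`).
#' @return numeric vector of length 19 with attribute `empty_blocks`.
#' @export
summary_vector <- function(hists) {
  blocks <- c("n_if", "distance_rank", "position_rank", "turning_rank")
  v <- unlist(purrr::map(blocks, function(b) {
    hists$proportion[hists$block == b]
  }))
  stopifnot(length(v) == 19)
  attr(v, "empty_blocks") <- blocks[purrr::map_lgl(blocks, function(b) {
    any(hists$empty[hists$block == b])
  })]
  v
}

#' Cosine similarity of two summary vectors
#'
#' `dot(a, b) / (||a|| ||b||)`; 1 means identical proportion profiles,
#' 0 means maximally different. Nonnegative for proportion-valued inputs.
#'
#' @param a,b numeric vectors of equal length with nonzero norm.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(a * b) / (na * nb)
}

#' Parameter-comparison matrix over the 40-combination sweep
#'
#' Runs the identification stage of the pipeline for every combination of
#' the sweep grid on a fixed dataset and compares the resulting
#' 19-dimensional summary vectors pairwise by cosine similarity. Delay
#' tracks depend only on `w`, so they are computed once per `w` and reused
#' across the eight (c_min, eps) pairs sharing it. A combination that
#' fails (e.g. no surviving records) leaves its row/column `NA`.
#'
#' @param analyses_by_w function taking a `w` value and returning the
#'   per-event raw material: a list of lists with elements `kin`, `events`,
#'   `pairs`, `delays` (see [sweep_material()]).
#' @param dt frame interval (s).
#' @param grid sweep grid; defaults to [sweep_grid()].
#' @return list with `similarity` (40 x 40 symmetric matrix, unit
#'   diagonal), `vectors` (19 x 40 matrix), `grid` (the combo ordering).
#' @export
similarity_matrix <- function(analyses_by_w, dt = 0.02,
                              grid = sweep_grid()) {
  ws <- unique(grid$w)
  material <- setNames(lapply(ws, analyses_by_w), as.character(ws))
  vectors <- matrix(NA_real_, nrow = 19, ncol = nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cfg <- analysis_config(w = grid$w[r], c_min = grid$c_min[r],
                           eps = grid$eps[r])
    mat <- material[[as.character(grid$w[r])]]
    res <- tryCatch({
      anl <- purrr::map(mat, function(m) {
        finish_analysis(m, cfg, dt)
      })
      summary_vector(rank_histograms(anl, n_fish = 5))
    }, error = function(e) NULL)
    if (!is.null(res)) vectors[, r] <- res
  }
  n <- nrow(grid)
  sim <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      a <- vectors[, i]; b <- vectors[, j]
      if (!anyNA(a) && !anyNA(b) && sum(a^2) > 0 && sum(b^2) > 0) {
        sim[i, j] <- sim[j, i] <- cosine_similarity(a, b)
      }
    }
  }
  diag(sim)[!is.na(diag(sim))] <- 1
  list(similarity = sim, vectors = vectors, grid = grid)
}

#' Precompute per-w sweep material for a set of recordings
#'
#' Delay extraction is the expensive stage and depends only on `w`; the
#' identification thresholds act afterwards. This helper computes
#' kinematics, U-turn events, pair geometry and delay tracks once per
#' recording for a given `w`, for reuse by [similarity_matrix()].
#'
#' @param ts_list list of `trajectory_set`s (one collective U-turn each).
#' @param w correlation half-window (frames).
#' @param tau_max delay-grid cap (frames).
#' @return list (one element per recording) of lists `kin, events, pairs,
#'   delays, dt`.
#' @export
sweep_material <- function(ts_list, w, tau_max = 100) {
  purrr::map(ts_list, function(ts) {
    kin <- compute_kinematics(ts)
    cfg <- analysis_config(w = w, tau_max = tau_max)
    pairs <- pair_geometry(kin)
    list(kin = kin, events = detect_uturns(kin), pairs = pairs,
         dranks = distance_rank(pairs), pranks = position_rank(kin),
         delays = extract_all_delays(kin, cfg),
         dt = attr(kin, "dt"))
  })
}

# identification + windowing for one recording's precomputed material
finish_analysis <- function(m, cfg, dt) {
  records <- identify_influential(m$delays, cfg, dt = dt)
  events <- m$events
  if (nrow(events) > 0) {
    ev1 <- dplyr::filter(tibble::as_tibble(events),
                         .data$event_id == min(.data$event_id))
    t_s <- ev1$t_s[1]; t_e <- ev1$t_e[1]
    dur <- t_e - t_s
    win <- c(t_s - dur, t_e + dur)
    kin_w <- dplyr::filter(tibble::as_tibble(m$kin),
                           .data$time >= win[1], .data$time <= win[2])
    records <- dplyr::filter(records, .data$time >= win[1],
                             .data$time <= win[2])
    class(records) <- c("influence_records", class(tibble::tibble()))
    nif <- eta_series(count_influential(records, kin_w))
    nif$t_bar <- normalized_time(nif$time, t_s, t_e)
  } else {
    nif <- eta_series(count_influential(records, m$kin))
    nif$t_bar <- NA_real_
  }
  structure(list(kin = m$kin, events = events, pairs = m$pairs,
                 dranks = m$dranks, pranks = m$pranks,
                 delays = m$delays, records = records, nif = nif,
                 config = cfg),
            class = "uturn_analysis")
}

#' Data retention as a function of the correlation threshold
#'
#' For each `c_min`, counts the (focal fish, frame) data points with at
#' least one neighbor surviving the correlation and reaction-time gates,
#' and the fraction relative to the count at `c_min = 0.5`. Retention is
#' nonincreasing in `c_min` by construction; the multi-influencer
#' tolerance plays no role here since it only selects among survivors.
#'
#' @param delays a `delay_track` tibble over all pairs
#'   ([extract_all_delays()]).
#' @param c_min_values thresholds to evaluate.
#' @param config an [analysis_config()] supplying `tau_r`.
#' @param dt frame interval (s).
#' @return tibble `c_min, count, fraction`.
#' @export
retention_curve <- function(delays, c_min_values = c(0.995, 0.99, 0.95, 0.5),
                            config = analysis_config(), dt = 0.02) {
  d <- tibble::as_tibble(delays) |>
    dplyr::filter(!is.na(.data$gamma),
                  .data$tau_star * dt > config$tau_r)
  counts <- purrr::map_int(c_min_values, function(cm) {
    d |>
      dplyr::filter(.data$gamma > cm) |>
      dplyr::distinct(.data$focal, .data$frame) |>
      nrow()
  })
  base <- d |>
    dplyr::filter(.data$gamma > 0.5) |>
    dplyr::distinct(.data$focal, .data$frame) |>
    nrow()
  tibble::tibble(c_min = c_min_values, count = counts,
                 fraction = if (base > 0) counts / base else NA_real_)
}
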