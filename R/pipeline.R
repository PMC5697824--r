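#' Run the full influence analysis on one recording
#'
#' Convenience wrapper chaining the pipeline stages on a trajectory set
#' containing (at least) one collective U-turn: kinematics, U-turn
#' detection, pairwise delay extraction, influential-neighbor
#' identification, optional chain removal, and per-fish influential-
#' neighbor counts over the analysis span (normalized time in
#' `[-1, 2]` around the first detected event by default).
#'
#' @param ts a `trajectory_set` (gap-interpolated if needed).
#' @param config an [analysis_config()].
#' @param persistence,min_abs_sin,assoc_window,span passed to
#'   [detect_uturns()].
#' @param remove_chains drop chain-of-influence records
#'   ([remove_influence_chains()])? Default `FALSE`, matching the finding
#'   that chains barely alter the statistics.
#' @param tbar_span normalized-time analysis span around the event.
#' @return list of class `uturn_analysis`: `kin`, `events`
#'   (`uturn_events`), `pairs`, `delays`, `records`, `nif` (with `eta`),
#'   `config`. `events` may have zero rows when no complete collective
#'   U-turn is found; downstream elements are then empty.
#' @export
analyze_uturn <- function(ts, config = analysis_config(),
                          persistence = 25, min_abs_sin = 0.5,
                          assoc_window = 3, span = 50,
                          remove_chains = FALSE, tbar_span = c(-1, 2)) {
  kin <- compute_kinematics(ts)
  events <- detect_uturns(kin, persistence = persistence,
                          min_abs_sin = min_abs_sin,
                          assoc_window = assoc_window, span = span)
  dt <- attr(kin, "dt")
  delays <- extract_all_delays(kin, config)
  records <- identify_influential(delays, config, dt = dt)
  if (remove_chains) records <- remove_influence_chains(records)
  pairs <- pair_geometry(kin)
  if (nrow(events) > 0) {
    ev1 <- dplyr::filter(tibble::as_tibble(events),
                         .data$event_id == min(.data$event_id))
    t_s <- ev1$t_s[1]; t_e <- ev1$t_e[1]
    dur <- t_e - t_s
    win <- c(t_s + tbar_span[1] * dur, t_s + tbar_span[2] * dur)
    kin_w <- dplyr::filter(tibble::as_tibble(kin),
                           .data$time >= win[1], .data$time <= win[2])
    records <- dplyr::filter(records, .data$time >= win[1],
                             .data$time <= win[2])
    class(records) <- c("influence_records", class(tibble::tibble()))
    nif <- eta_series(count_influential(records, kin_w))
    nif$t_bar <- normalized_time(nif$time, t_s, t_e)
  } else {
    nif <- eta_series(count_influential(records, kin))
    nif$t_bar <- NA_real_
  }
  structure(list(kin = kin, events = events, pairs = pairs,
                 delays = delays, records = records, nif = nif,
                 config = config),
            class = "uturn_analysis")
}

#' @export
print.uturn_analysis <- function(x, ...) {
  cat(sprintf(
    "<uturn_analysis> %d event(s), %d influence records, %d fish\n",
    length(unique(x$events$event_id)), nrow(x$records),
    length(unique(tibble::as_tibble(x$kin)$id))))
  invisible(x)
}

#' One-row summary of an analysis run
#' @param x an `uturn_analysis`.
#' @param ... unused.
#' @return one-row tibble with event count, record count, mean delay,
#'   mean number of influential neighbors, and modal `N_if`.
#' @export
glance.uturn_analysis <- function(x, ...) {
  tab <- table(x$nif$n_if)
  tibble::tibble(
    n_events = length(unique(x$events$event_id)),
    n_records = nrow(x$records),
    mean_tau = if (nrow(x$records)) mean(x$records$tau) else NA_real_,
    mean_n_if = mean(x$nif$n_if),
    modal_n_if = if (length(tab)) {
      as.integer(names(tab)[which.max(tab)])
    } else {
      NA_integer_
    })
}

#' Export influence records as delimited text
#'
#' Writes the time-resolved influence-network edge list
#' (`t, focal, neighbor, tau_s, C`).
#'
#' @param records an `influence_records` tibble.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_influence_records <- function(records, path) {
  out <- tibble::as_tibble(records) |>
    dplyr::transmute(t = .data$time, focal = .data$focal,
                     neighbor = .data$neighbor, tau_s = .data$tau,
                     C = .data$C)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Export detected U-turn events as JSON
#'
#' @param events an `uturn_events` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_uturn_events <- function(events, path) {
  evs <- split(tibble::as_tibble(events), events$event_id)
  payload <- purrr::map(evs, function(ev) {
    list(event_id = ev$event_id[1],
         direction_before = ev$direction_before[1],
         direction_after = ev$direction_after[1],
         t_s = ev$t_s[1], t_e = ev$t_e[1],
         fish = purrr::pmap(
           ev[, c("id", "t_s_i", "t_m_i", "t_e_i", "thr_s", "thr_e",
                  "turning_rank")],
           function(id, t_s_i, t_m_i, t_e_i, thr_s, thr_e, turning_rank) {
             list(id = id, t_s_i = t_s_i, t_m_i = t_m_i, t_e_i = t_e_i,
                  thr_s = thr_s, thr_e = thr_e,
                  turning_rank = turning_rank)
           }))
  })
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
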