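# Structured and null ensembles shared by the acceptance checks.
# The structured ensemble uses the chain configuration: direct edges plus
# chain shortcuts give each fish more than one genuine correlate, as in
# real schools; the null ensemble is bootstrapped from its tracks.

chain_config <- function(seed) {
  sim_config(n_fish = 5, duration = 12, uturn_times = 6,
             influence_graph = list(
               `2` = list(influencer = "1", delay = 10),
               `3` = list(influencer = "2", delay = 12),
               `4` = list(influencer = "3", delay = 14),
               `5` = list(influencer = "4", delay = 16)),
             kappa = 100, seed = seed)
}

structured_ensemble <- function(n_events = 200, seed0 = 1000) {
  cached(paste0("structured_", n_events), function() {
    analyses <- list(); pools <- list()
    i <- 0
    while (length(analyses) < n_events) {
      i <- i + 1
      sim <- simulate_school(chain_config(seed0 + i))
      an <- analyze_uturn(sim$trajectories)
      if (nrow(an$events) == 0) next
      analyses[[length(analyses) + 1]] <- an
      pools[[length(pools) + 1]] <-
        uturn_track_pool(sim$trajectories, an$events) |>
        dplyr::mutate(source_event = paste0(i, "_", source_event))
    }
    list(analyses = analyses, pool = dplyr::bind_rows(pools))
  })
}

null_ensemble <- function(n_events = 200, seed = 2024) {
  cached(paste0("null_", n_events), function() {
    pool <- structured_ensemble(n_events)$pool
    ens <- generate_null_ensemble(pool, null_config(n_events = n_events),
                                  seed = seed)
    ens$analyses[!vapply(ens$analyses, is.null, logical(1))]
  })
}
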