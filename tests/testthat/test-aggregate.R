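analysis_star <- function() {
  cached("analysis_star", function() {
    analyze_uturn(fixture_suite()$star5$trajectories)
  })
}

test_that("rank histograms are normalized and reflect implanted structure", {
  an <- analysis_star()
  h <- rank_histograms(an, n_fish = 5)
  for (b in unique(h$block)) {
    expect_equal(sum(h$proportion[h$block == b]), 1, tolerance = 1e-12)
    expect_true(all(h$proportion[h$block == b] >= 0))
  }
  expect_equal(nrow(h), 5 + 4 + 5 + 5)
  # star fixture: one influencer dominates, so N_if mass peaks at 1
  nif_block <- h[h$block == "n_if", ]
  expect_equal(nif_block$value[which.max(nif_block$proportion)], 1)
})

test_that("empty influence sets give an explicit empty distance-rank block", {
  an <- analysis_star()
  an_empty <- an
  an_empty$records <- an$records[0, ]
  an_empty$nif <- dplyr::mutate(an$nif, n_if = 0L)
  h <- rank_histograms(an_empty, n_fish = 5)
  expect_true(all(h$empty[h$block == "distance_rank"]))
  expect_equal(h$proportion[h$block == "n_if"][1], 1) # all mass at 0
})

test_that("time course reproduces constants and averages across events", {
  mk_const <- function(speed) {
    df <- dplyr::bind_rows(
      linear_track("1", 400, x0 = -200, y0 = 300, vx = speed),
      linear_track("2", 400, x0 = -220, y0 = 300, vx = speed))
    kin <- compute_kinematics(make_ts(df))
    ev <- tibble::tibble(
      event_id = 1L, id = c("1", "2"), t_s_i = 2, t_m_i = 3, t_e_i = 4,
      thr_s = 1, thr_e = 1, direction_before = "anticlockwise",
      direction_after = "clockwise", turning_rank = 1:2, t_s = 2, t_e = 4)
    class(ev) <- c("uturn_events", class(ev))
    nif <- count_influential(rec_tbl(frame = integer(0), focal = character(0),
                                     neighbor = character(0)),
                             tibble::as_tibble(kin)[, c("frame", "time", "id")])
    nif <- eta_series(nif)
    nif$t_bar <- normalized_time(nif$time, 2, 4)
    structure(list(kin = kin, events = ev, pairs = pair_geometry(kin),
                   records = rec_tbl(frame = integer(0), focal = character(0),
                                     neighbor = character(0)),
                   nif = nif, config = analysis_config()),
              class = "uturn_analysis")
  }
  tc1 <- time_course(mk_const(100))
  inside <- !is.na(tc1$V)
  expect_true(any(inside))
  expect_true(all(abs(tc1$V[inside] - 100) < 1e-6))
  tc2 <- time_course(list(mk_const(100), mk_const(200)))
  inside2 <- !is.na(tc2$V)
  expect_true(all(abs(tc2$V[inside2] - 150) < 1e-6))
  # constant headings: polarization exactly 1 wherever defined
  expect_true(all(abs(tc1$P[!is.na(tc1$P)] - 1) < 1e-9))
})

test_that("polarization time course is V-shaped across a scripted cascade", {
  an <- cached("analysis_chain", function() {
    analyze_uturn(fixture_suite()$chain5$trajectories)
  })
  tc <- time_course(an)
  mid <- tc$P[tc$t_bar >= 0.2 & tc$t_bar <= 0.8]
  edge <- tc$P[(tc$t_bar < -0.5 | tc$t_bar > 1.5) & !is.na(tc$P)]
  expect_lt(min(mid, na.rm = TRUE), 0.75)
  expect_gt(mean(edge, na.rm = TRUE), 0.9)
})

test_that("spatial map places records in the focal frame and is rotation invariant", {
  # neighbor ahead at 65 mm, 5 mm to the side, for every record (kept
  # off the cell edges so the assignment is float-robust)
  df <- dplyr::bind_rows(
    linear_track("1", 20, x0 = 0, y0 = 300, vx = 100),
    linear_track("2", 20, x0 = 65, y0 = 305, vx = 100))
  kin <- compute_kinematics(make_ts(df))
  pairs <- pair_geometry(kin)
  rec <- rec_tbl(frame = 5:15, focal = "1", neighbor = "2")
  sm <- spatial_map(rec, pairs, cell = 20)
  expect_equal(nrow(sm$cells), 1)
  expect_equal(sm$cells$cx, -10) # ahead is +y; 65 mm -> cell [60, 80)
  expect_equal(sm$cells$cy, 70)
  expect_equal(sm$cells$count, sm$n_records)
  expect_equal(sum(sm$cells$count), nrow(rec))

  # rotate the whole scene: focal-frame map unchanged
  a <- 2.1
  df_r <- dplyr::mutate(df, xn = x * cos(a) - y * sin(a),
                        yn = x * sin(a) + y * cos(a), x = xn, y = yn,
                        xn = NULL, yn = NULL)
  pairs_r <- pair_geometry(compute_kinematics(make_ts(df_r)))
  sm_r <- spatial_map(rec, pairs_r, cell = 20)
  expect_equal(sm_r$cells$cx, sm$cells$cx)
  expect_equal(sm_r$cells$cy, sm$cells$cy)
  expect_equal(sm_r$cells$count, sm$cells$count)
})

test_that("angle and distance distributions separate influential pairs from all pairs", {
  df <- dplyr::bind_rows(
    linear_track("1", 20, x0 = 0, y0 = 300, vx = 100),
    linear_track("2", 20, x0 = 60, y0 = 300, vx = 100),
    linear_track("3", 20, x0 = -40, y0 = 260, vx = 100))
  kin <- compute_kinematics(make_ts(df))
  pairs <- pair_geometry(kin)
  rec <- rec_tbl(frame = 5, focal = "1", neighbor = "2")
  add <- angle_distance_distributions(rec, pairs)
  s_inf <- add$summary[add$summary$set == "influential", ]
  expect_equal(s_inf$mean[s_inf$variable == "d"], 60)
  expect_equal(s_inf$sd[s_inf$variable == "d"], 0)
  # influential set == all pairs: identical histograms
  rec_all <- pairs |>
    dplyr::mutate(tau = 0.2, tau_frames = 10, C = 0.99) |>
    dplyr::select(time, frame, focal, neighbor, tau, tau_frames, C)
  add2 <- angle_distance_distributions(rec_all, pairs)
  h_inf <- add2$histograms[add2$histograms$set == "influential", ]
  h_all <- add2$histograms[add2$histograms$set == "all_pairs", ]
  expect_equal(dplyr::arrange(h_inf[, c("variable", "bin_lo", "count")],
                              variable, bin_lo),
               dplyr::arrange(h_all[, c("variable", "bin_lo", "count")],
                              variable, bin_lo))
  # star fixture: influential viewing angles are narrower than all pairs
  an <- analysis_star()
  add3 <- angle_distance_distributions(an$records, an$pairs)
  sd_inf <- add3$summary$sd[add3$summary$set == "influential" &
                              add3$summary$variable == "theta"]
  sd_all <- add3$summary$sd[add3$summary$set == "all_pairs" &
                              add3$summary$variable == "theta"]
  expect_lt(sd_inf, sd_all)
})

test_that("delay maps average tau per (heading difference, distance) bin", {
  df <- dplyr::bind_rows(
    linear_track("1", 20, x0 = 0, y0 = 300, vx = 100),
    linear_track("2", 20, x0 = 60, y0 = 300, vx = 100))
  kin <- compute_kinematics(make_ts(df))
  pairs <- pair_geometry(kin)
  rec <- rec_tbl(frame = 5:15, focal = "1", neighbor = "2", tau = 0.4)
  dm <- delay_map(rec, pairs)
  expect_true(all(dm$mean_tau == 0.4))
  expect_equal(sum(dm$count), nrow(rec))
  # empty bins are absent, not zero
  expect_false(any(dm$mean_tau == 0))
})

test_that("delay grows with distance when the generator implants it", {
  # two pairs at different distances and delays pooled into one map
  mk <- function(gap, tau, id2) {
    dplyr::bind_rows(
      linear_track("1", 20, x0 = 0, y0 = 300, vx = 100),
      linear_track(id2, 20, x0 = gap, y0 = 300, vx = 100))
  }
  df <- dplyr::bind_rows(
    linear_track("1", 20, x0 = 0, y0 = 300, vx = 100),
    linear_track("2", 20, x0 = 50, y0 = 300, vx = 100),
    linear_track("3", 20, x0 = 110, y0 = 300, vx = 100))
  kin <- compute_kinematics(make_ts(df))
  pairs <- pair_geometry(kin)
  rec <- dplyr::bind_rows(
    rec_tbl(frame = 5:15, focal = "1", neighbor = "2", tau = 0.2),
    rec_tbl(frame = 5:15, focal = "1", neighbor = "3", tau = 0.5))
  dm <- delay_map(rec, pairs, d_bin = 20)
  dm <- dm[order(dm$d_lo), ]
  expect_true(all(diff(dm$mean_tau) >= 0))
})
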