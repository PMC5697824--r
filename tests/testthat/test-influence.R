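test_that("directional correlation is the cosine of the heading difference", {
  expect_equal(directional_correlation(0, 0), 1)
  expect_equal(directional_correlation(0, pi), -1)
  expect_equal(directional_correlation(0, pi / 2), 0)
  phi <- runif(20, -pi, pi); psi <- runif(20, -pi, pi)
  expect_true(all(abs(directional_correlation(phi, psi)) <= 1))
  expect_true(is.na(directional_correlation(NA, 0)))
})

test_that("windowed correlation averages H over 2w+1 frames and masks missing history", {
  # build a 2-fish set with known headings: both move straight
  df <- dplyr::bind_rows(
    linear_track("1", 40, x0 = 260, y0 = 0, vx = 100, vy = 0),
    linear_track("2", 40, x0 = 280, y0 = 20, vx = 100, vy = 0))
  kin <- compute_kinematics(make_ts(df))
  # identical constant headings: H = 1 everywhere available
  expect_equal(windowed_correlation(kin, "1", "2", t = 0.4, tau = 5, w = 2), 1)
  # w = 0 equals the raw H
  expect_equal(windowed_correlation(kin, "1", "2", t = 0.4, tau = 5, w = 0), 1)
  # insufficient history is masked, not zero-filled
  expect_true(is.na(windowed_correlation(kin, "1", "2", t = 0.04, tau = 10,
                                         w = 2)))
  fld <- correlation_field(kin, "1", "2", w = 2, tau_max = 10)
  expect_true(all(is.na(fld$C[1:2, ]))) # no full window at the record edge
  expect_true(all(fld$C[!is.na(fld$C)] >= -1 & fld$C[!is.na(fld$C)] <= 1))
})

test_that("windowed correlation equals the arithmetic mean of H values", {
  # H across the window (1, 0.5, 0, -0.5, -1) -> mean 0; engineered via
  # focal headings rotating against a fixed neighbor heading
  angles_i <- c(0, acos(0.5), pi / 2, acos(-0.5), pi)
  h <- directional_correlation(angles_i, rep(0, 5))
  expect_equal(mean(h), 0)
  h2 <- rep(0.9, 5)
  expect_equal(mean(h2), 0.9)
})

test_that("delay recursion equals the brute-force constrained argmax oracle", {
  # 200-frame noiseless pair fixture with lag 20
  cfg <- sim_config(n_fish = 2, duration = 4, uturn_times = 2,
                    influence_graph = list(`2` = list(influencer = "1",
                                                      delay = 20)),
                    kappa = Inf, seed = 11)
  kin <- compute_kinematics(simulate_school(cfg)$trajectories)
  kin <- kin[kin$frame < 200, ]
  phi2 <- kin_phi(kin, "2"); phi1 <- kin_phi(kin, "1")
  for (pars in list(c(w = 2, tau0 = 50), c(w = 0, tau0 = 50),
                    c(w = 3, tau0 = 30))) {
    acfg <- analysis_config(w = pars["w"], tau0 = pars["tau0"],
                            tau_max = 100)
    dt_track <- extract_delays(kin, "2", "1", acfg)
    orc <- oracle_delays(phi2, phi1, w = pars[["w"]],
                         tau0 = pars[["tau0"]], tau_max = 100)
    expect_identical(dt_track$tau_star, orc$tau_star)
    expect_equal(dt_track$gamma, orc$gamma, tolerance = 1e-12)
  }
  # noisy fixture too
  cfgn <- sim_config(n_fish = 2, duration = 4, uturn_times = 2,
                     influence_graph = list(`2` = list(influencer = "1",
                                                       delay = 20)),
                     kappa = 100, seed = 12)
  kin2 <- compute_kinematics(simulate_school(cfgn)$trajectories)
  kin2 <- kin2[kin2$frame < 200, ]
  d2 <- extract_delays(kin2, "2", "1", analysis_config())
  o2 <- oracle_delays(kin_phi(kin2, "2"), kin_phi(kin2, "1"),
                      w = 2, tau0 = 50, tau_max = 100)
  expect_identical(d2$tau_star, o2$tau_star)
})

test_that("delay recursion recovers exact lags and obeys its invariants", {
  kin <- pair_kin("pair_lag20")
  d <- extract_delays(kin, "2", "1", analysis_config())
  post <- d$tau_star[!is.na(d$tau_star)]
  expect_gte(mean(post == 20), 0.95)
  # growth bound tau*_k <= tau*_{k-1} + 1 on consecutive defined frames
  ts_def <- d$tau_star[!is.na(d$tau_star)]
  expect_true(all(diff(ts_def) <= 1))
  # identical series: smallest-tau tie-break gives 0
  df <- dplyr::bind_rows(circular_track("1", 300), circular_track("2", 300))
  kin_id <- compute_kinematics(make_ts(df))
  d0 <- extract_delays(kin_id, "2", "1", analysis_config())
  expect_true(all(d0$tau_star[!is.na(d0$tau_star)] == 0))
})

test_that("search range follows [0, tau_prev + 1]", {
  # identical series lock tau at 0; a probe field confirms the range cap:
  # after a frame with tau* = t, the next frame never exceeds t + 1
  kin <- pair_kin("pair_lag20_noisy")
  d <- extract_delays(kin, "2", "1", analysis_config())
  tau <- d$tau_star[!is.na(d$tau_star)]
  expect_true(all(diff(tau) <= 1))
  expect_true(all(tau >= 0 & tau <= 100))
})

test_that("influential-neighbor identification applies both gates and the epsilon rule", {
  dt <- 0.02
  mk <- function(neighbor, tau_frames, gamma) {
    tibble::tibble(focal = "1", neighbor = neighbor, frame = 100,
                   time = 2, tau_star = tau_frames, gamma = gamma)
  }
  cfg <- analysis_config() # c_min 0.95, eps 3, tau_r 0.04
  # single neighbor, C = 0.99 at 0.4 s: influential
  r1 <- identify_influential(mk("2", 20, 0.99), cfg, dt = dt)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$tau, 0.4)
  # same correlation at 0.02 s: below the reaction-time floor
  r2 <- identify_influential(mk("2", 1, 0.99), cfg, dt = dt)
  expect_equal(nrow(r2), 0)
  # boundary: tau = tau_R exactly is excluded (strict inequality)
  r2b <- identify_influential(mk("2", 2, 0.99), cfg, dt = dt)
  expect_equal(nrow(r2b), 0)
  # epsilon rule: scores (0.99, 0.97, 0.90) keep the first two
  d3 <- dplyr::bind_rows(mk("2", 20, 0.99), mk("3", 15, 0.97),
                         mk("4", 10, 0.90))
  r3 <- identify_influential(d3, cfg, dt = dt)
  expect_setequal(r3$neighbor, c("2", "3"))
})

test_that("influential-neighbor counts and eta follow their definitions", {
  grid <- tidyr::expand_grid(frame = 0:9, id = c("1", "2", "3")) |>
    dplyr::mutate(time = frame * 0.02)
  rec <- dplyr::bind_rows(
    rec_tbl(frame = 5, focal = "1", neighbor = "2"),
    rec_tbl(frame = 5, focal = "1", neighbor = "3"),
    rec_tbl(frame = 6, focal = "1", neighbor = "2"))
  nif <- count_influential(rec, grid)
  expect_equal(nif$n_if[nif$id == "1" & nif$frame == 5], 2L)
  expect_equal(nif$n_if[nif$id == "1" & nif$frame == 6], 1L)
  expect_equal(nif$n_if[nif$id == "1" & nif$frame == 0], 0L)
  expect_true(all(nif$n_if[nif$id == "2"] == 0L))

  eta <- eta_series(nif)
  e1 <- eta[eta$id == "1", ]
  expect_equal(e1$eta[e1$frame == 5], 0.5) # 2 -> 1
  expect_equal(e1$eta[e1$frame == 6], 1)   # 1 -> 0
  expect_true(is.na(e1$eta[e1$frame == 4])) # zero denominator
  # constant nonzero count: eta = 0
  rec_c <- rec_tbl(frame = 0:9, focal = "2", neighbor = "1")
  eta_c <- eta_series(count_influential(rec_c, grid))
  e2 <- eta_c[eta_c$id == "2", ]
  expect_true(all(e2$eta[1:9] == 0))
})

test_that("chain-of-influence removal follows the stated rule and is idempotent", {
  r <- function(f, n) rec_tbl(frame = 1, focal = f, neighbor = n)
  # {(1<-2), (1<-3), (2<-3)} -> drop (1,2)
  recs <- dplyr::bind_rows(r(1, 2), r(1, 3), r(2, 3))
  out <- remove_influence_chains(recs)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_setequal(paste(out$focal, out$neighbor), c("1 3", "2 3"))
  # no 2<->3 link: unchanged
  recs2 <- dplyr::bind_rows(r(1, 2), r(1, 3))
  out2 <- remove_influence_chains(recs2)
  expect_equal(attr(out2, "n_removed"), 0L)
  # mutual pair: both of focal 1's edges drop
  recs3 <- dplyr::bind_rows(r(1, 2), r(1, 3), r(2, 3), r(3, 2))
  out3 <- remove_influence_chains(recs3)
  expect_setequal(paste(out3$focal, out3$neighbor), c("2 3", "3 2"))
  # never adds records; idempotent
  for (rr in list(recs, recs2, recs3)) {
    o1 <- remove_influence_chains(rr)
    expect_lte(nrow(o1), nrow(rr))
    o2 <- remove_influence_chains(o1)
    expect_equal(as.data.frame(o2), as.data.frame(o1), ignore_attr = TRUE)
  }
})

test_that("global delay maximizes the time-averaged correlation", {
  kin <- pair_kin("pair_lag20")
  g <- global_delay(kin, "2", "1", tau_max = 60)
  expect_equal(g$tau_star, 20)
  # identical series: smallest tau on ties
  df <- dplyr::bind_rows(circular_track("1", 200), circular_track("2", 200))
  kin_id <- compute_kinematics(make_ts(df))
  g0 <- global_delay(kin_id, "2", "1")
  expect_equal(g0$tau_star, 0)
})

test_that("a single global delay misrepresents a lag that changes mid-record", {
  # two halves with different true lags: the whole-record delay is a
  # compromise that matches neither half's own estimate
  mk_half <- function(lag, seed) {
    cfg <- sim_config(n_fish = 2, duration = 8, uturn_times = 4,
                      influence_graph = list(`2` = list(influencer = "1",
                                                        delay = lag)),
                      kappa = Inf, seed = seed)
    compute_kinematics(simulate_school(cfg)$trajectories)
  }
  kin_a <- mk_half(16, 21)
  kin_b <- mk_half(48, 22)
  g_a <- global_delay(kin_a, "2", "1")$tau_star
  g_b <- global_delay(kin_b, "2", "1")$tau_star
  expect_equal(g_a, 16)
  expect_equal(g_b, 48)
  # concatenate the two recordings on one clock
  b <- tibble::as_tibble(kin_b)
  a <- tibble::as_tibble(kin_a)
  b$time <- b$time + max(a$time) + 0.02
  b$frame <- b$frame + max(a$frame) + 1
  joint <- dplyr::bind_rows(a, b)
  class(joint) <- class(kin_a); attr(joint, "dt") <- 0.02
  g_ab <- global_delay(joint, "2", "1")$tau_star
  # one value cannot represent both regimes: it must misdescribe at least
  # one half by more than the per-half estimation error
  expect_true(abs(g_ab - 16) > 2 || abs(g_ab - 48) > 2)
  expect_true(g_ab >= 0 && g_ab <= 100)
})

test_that("global rotation leaves delay tracks and influence sets unchanged", {
  fx <- fixture_suite()
  ts <- fx$pair_lag20_noisy$trajectories
  rot <- tibble::as_tibble(ts)
  a <- 0.87
  xn <- rot$x * cos(a) - rot$y * sin(a)
  yn <- rot$x * sin(a) + rot$y * cos(a)
  rot$x <- xn; rot$y <- yn
  ts_r <- as_trajectory_set(rot, traj_geometry(ts))
  cfg <- analysis_config()
  d0 <- extract_delays(compute_kinematics(ts), "2", "1", cfg)
  d1 <- extract_delays(compute_kinematics(ts_r), "2", "1", cfg)
  # identical up to floating-point ties in the argmax
  same <- d0$tau_star == d1$tau_star
  expect_gt(mean(same, na.rm = TRUE), 0.99)
  expect_equal(d0$gamma, d1$gamma, tolerance = 1e-9)
  r0 <- identify_influential(d0, cfg)
  r1 <- identify_influential(d1, cfg)
  expect_lt(abs(nrow(r0) - nrow(r1)), 3)
})
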