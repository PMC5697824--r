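test_that("heading and wall incidence match analytic motions", {
  # tangential anticlockwise motion on a circle: theta_w ~ +pi/2
  ts <- make_ts(circular_track("1", 200, r = 300, omega = 0.4))
  kin <- compute_kinematics(ts)
  inner <- 5:195 # away from one-sided ends
  expect_true(all(abs(abs(kin$theta_w[inner]) - pi / 2) < 0.02))
  expect_true(all(sin(kin$theta_w[inner]) > 0))

  # radial outward motion: phi = psi so theta_w ~ 0
  df <- linear_track("1", 100, x0 = 260, y0 = 0, vx = 80, vy = 0)
  kin2 <- compute_kinematics(make_ts(df))
  expect_true(all(abs(kin2$theta_w) < 1e-9))

  # motion toward the center: |theta_w| = pi
  df3 <- linear_track("1", 100, x0 = 340, y0 = 0, vx = -80, vy = 0)
  kin3 <- compute_kinematics(make_ts(df3))
  expect_true(all(abs(abs(kin3$theta_w) - pi) < 1e-9))
})

test_that("heading carries forward below the speed floor", {
  df <- linear_track("1", 60, x0 = 260, y0 = 0, vx = 100, vy = 0)
  df$x[31:60] <- df$x[30] # fish stops
  kin <- compute_kinematics(make_ts(df), speed_floor = 1)
  expect_equal(kin$phi[40:60], rep(0, 21))
  # all-stationary track has no defined heading at all
  dfs <- linear_track("1", 30, vx = 0, vy = 0)
  expect_error(compute_kinematics(make_ts(dfs)), "floor")
})

test_that("polarization matches closed forms", {
  expect_equal(polarization(rep(0.7, 5)), 1)
  expect_equal(polarization(c(0, pi)), 0)
  expect_equal(polarization(c(0, pi / 2)), sqrt(2) / 2)
  expect_true(is.na(polarization(c(0, NA))))
  # always within [0, 1]; equals 1 iff identical headings
  set.seed(7)
  for (i in 1:20) {
    phi <- runif(5, -pi, pi)
    p <- polarization(phi)
    expect_true(p >= 0 && p <= 1 + 1e-12)
    expect_lt(p, 1)
  }
})

test_that("pair geometry matches right-angle constructions", {
  df <- dplyr::bind_rows(
    linear_track("1", 10, x0 = 0, y0 = 50, vx = 100, vy = 0),
    linear_track("2", 10, x0 = 0, y0 = 150, vx = 100, vy = 0))
  pg <- pair_geometry(compute_kinematics(make_ts(df)))
  p12 <- pg[pg$focal == "1" & pg$neighbor == "2", ]
  expect_equal(p12$d, rep(100, 10))
  expect_equal(p12$theta_view, rep(pi / 2, 10))
  expect_equal(p12$phi_diff, rep(0, 10))
  # neighbor dead ahead: theta = 0
  df2 <- dplyr::bind_rows(
    linear_track("1", 10, x0 = 0, y0 = 50, vx = 100, vy = 0),
    linear_track("2", 10, x0 = 50, y0 = 50, vx = 100, vy = 0))
  pg2 <- pair_geometry(compute_kinematics(make_ts(df2)))
  expect_equal(pg2$theta_view[pg2$focal == "1"], rep(0, 10))
})

test_that("rotation leaves P, d, theta, phi_diff, theta_w unchanged and mirroring flips signs", {
  base <- dplyr::bind_rows(circular_track("1", 80, psi0 = 0.1),
                           circular_track("2", 80, psi0 = 0.35, r = 320))
  rot <- function(df, a) {
    dplyr::mutate(df, xn = x * cos(a) - y * sin(a),
                  yn = x * sin(a) + y * cos(a), x = xn, y = yn,
                  xn = NULL, yn = NULL)
  }
  kin0 <- compute_kinematics(make_ts(base))
  kin1 <- compute_kinematics(make_ts(rot(base, 1.234)))
  inner <- kin0$frame > 0 & kin0$frame < 79
  expect_equal(kin1$theta_w[inner], kin0$theta_w[inner], tolerance = 1e-9)
  expect_equal(polarization_series(kin1)$polarization,
               polarization_series(kin0)$polarization, tolerance = 1e-9)
  pg0 <- pair_geometry(kin0); pg1 <- pair_geometry(kin1)
  expect_equal(pg1$d, pg0$d, tolerance = 1e-9)
  expect_equal(pg1$theta_view, pg0$theta_view, tolerance = 1e-9)
  expect_equal(pg1$phi_diff, pg0$phi_diff, tolerance = 1e-9)

  mir <- dplyr::mutate(base, x = -x) # reflect across vertical axis
  kinm <- compute_kinematics(make_ts(mir))
  in_m <- kinm$frame > 0 & kinm$frame < 79
  expect_equal(kinm$theta_w[in_m], -kin0$theta_w[inner], tolerance = 1e-9)
  pgm <- pair_geometry(kinm)
  expect_equal(pgm$d, pg0$d, tolerance = 1e-9)
  expect_equal(pgm$theta_view, -pg0$theta_view, tolerance = 1e-9)
  expect_equal(pgm$phi_diff, -pg0$phi_diff, tolerance = 1e-9)
})

test_that("burst detection finds rising ramps of a sawtooth and nothing in constant speed", {
  dt <- 0.02
  n <- 400
  t <- (seq_len(n) - 1) * dt
  # sawtooth speed: rise 50 -> 200 mm/s over 0.2 s, fall back over 0.2 s
  period <- 0.4
  phase <- (t %% period) / period
  speed <- ifelse(phase < 0.5, 50 + 150 * phase / 0.5,
                  200 - 150 * (phase - 0.5) / 0.5)
  # integrate along +x to get positions with that speed profile
  x <- cumsum(c(0, speed[-n] * dt))
  df <- tibble::tibble(frame = seq_len(n) - 1, time = t, id = "1",
                       x = 0 + x, y = 300)
  bursts <- detect_bursts(compute_kinematics(make_ts(df)),
                          accel_threshold = 300, smooth_window = 5)
  iv <- bursts$intervals
  # one burst per rising ramp (ramp accel = 750 mm/s^2 > 300)
  n_ramps <- floor(max(t) / period) + 1
  expect_equal(nrow(iv), n_ramps)
  # burst onsets sit near the speed minima (ramp starts)
  on_phase <- (iv$onset_time %% period) / period
  expect_true(all(on_phase < 0.15 | on_phase > 0.9))

  cst <- linear_track("1", 100, x0 = 260, vx = 100)
  b2 <- detect_bursts(compute_kinematics(make_ts(cst)))
  expect_equal(nrow(b2$intervals), 0)
  expect_error(detect_bursts(compute_kinematics(make_ts(cst[1:3, ])),
                             smooth_window = 5), "short")
})

test_that("burst-influence overlap is 1 for an always-bursting influencer and ~1 under independence", {
  dt <- 0.02
  n <- 500
  fr <- tibble::tibble(frame = rep(0:(n - 1), 2),
                       time = rep((0:(n - 1)) * dt, 2),
                       id = rep(c("1", "2"), each = n),
                       bursting = c(rep(TRUE, n), rep(FALSE, n)))
  bursts <- structure(list(intervals = tibble::tibble(), frames = fr),
                      class = "burst_segmentation")
  rec <- rec_tbl(frame = 100:200, focal = "2", neighbor = "1", tau = 0.2)
  ov <- burst_influence_overlap(bursts, rec)
  s1 <- ov$stats[ov$stats$id == "1", ]
  expect_equal(s1$overlap_ratio, 1)

  # independence: random bursts, random influence times -> ratio ~ 1
  set.seed(42)
  burst_mask <- runif(n) < 0.3
  fr2 <- fr
  fr2$bursting <- c(burst_mask, rep(FALSE, n))
  bursts2 <- structure(list(intervals = tibble::tibble(), frames = fr2),
                       class = "burst_segmentation")
  frames <- sample(50:(n - 1), 3000, replace = TRUE)
  rec2 <- rec_tbl(frame = frames, focal = "2", neighbor = "1", tau = 0.2)
  ov2 <- burst_influence_overlap(bursts2, rec2)
  s2 <- ov2$stats[ov2$stats$id == "1", ]
  expect_lt(abs(s2$overlap_ratio - 1), 0.15)

  # no records: undefined marker
  ov3 <- burst_influence_overlap(bursts, rec[0, ])
  expect_true(all(is.na(ov3$stats$overlap_ratio)))
})
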