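# Shared fixtures and independent oracles. Heavy objects are memoized in
# `.fixture_cache` so each is built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_suite <- function() cached("suite", function() make_fixture_suite(seed = 1))

pair_kin <- function(which = "pair_lag20") {
  cached(paste0("kin_", which), function() {
    compute_kinematics(fixture_suite()[[which]]$trajectories)
  })
}

# small hand-built trajectory set: n fish on a common clock
make_ts <- function(df, geometry = ring_geometry(), dt = NULL) {
  as_trajectory_set(df, geometry, dt = dt)
}

# fish moving on a circle of radius r at angular speed omega (rad/s)
circular_track <- function(id, n, r = 300, omega = 0.4, psi0 = 0, dt = 0.02) {
  t <- (seq_len(n) - 1) * dt
  tibble::tibble(frame = seq_len(n) - 1, time = t, id = id,
                 x = r * cos(psi0 + omega * t),
                 y = r * sin(psi0 + omega * t))
}

# straight mover
linear_track <- function(id, n, x0 = 0, y0 = 300, vx = 100, vy = 0,
                         dt = 0.02) {
  t <- (seq_len(n) - 1) * dt
  tibble::tibble(frame = seq_len(n) - 1, time = t, id = id,
                 x = x0 + vx * t, y = y0 + vy * t)
}

# Brute-force constrained per-frame argmax oracle for the delay recursion.
# Recomputes H and the windowed mean with plain loops, then walks frames
# applying the search-range and smallest-delay rules independently of
# extract_delays.
oracle_delays <- function(phi_i, phi_j, w, tau0, tau_max) {
  M <- length(phi_i)
  cwin <- function(k, tau) {
    ks <- (k - w):(k + w)
    if (any(ks < 1) || any(ks > M) || any(ks - tau < 1)) return(NA_real_)
    vals <- cos(phi_i[ks] - phi_j[ks - tau])
    if (anyNA(vals)) return(NA_real_)
    mean(vals)
  }
  tau_star <- rep(NA_integer_, M)
  gamma <- rep(NA_real_, M)
  tau_prev <- tau0
  k_start <- min(tau0 + 1L, tau_max) + w + 2L
  if (k_start > M) return(list(tau_star = tau_star, gamma = gamma))
  for (k in k_start:M) {
    hi <- min(tau_prev + 1L, tau_max)
    best_tau <- NA_integer_; best_c <- -Inf
    for (tau in 0:hi) {
      cc <- cwin(k, tau)
      if (!is.na(cc) && cc > best_c) { # strict >: smallest tau on ties
        best_c <- cc; best_tau <- tau
      }
    }
    if (!is.na(best_tau)) {
      tau_star[k] <- best_tau
      gamma[k] <- best_c
      tau_prev <- best_tau
    }
  }
  list(tau_star = tau_star, gamma = gamma)
}

# headings (phi) of one fish out of a kinematics table, in time order
kin_phi <- function(kin, fish) {
  tr <- tibble::as_tibble(kin)
  tr <- tr[tr$id == fish, ]
  tr$phi[order(tr$time)]
}

# minimal influence-record tibble builder
rec_tbl <- function(frame, focal, neighbor, tau = 0.2, C = 0.99,
                    dt = 0.02) {
  tibble::tibble(time = frame * dt, frame = frame,
                 focal = as.character(focal),
                 neighbor = as.character(neighbor),
                 tau = tau, tau_frames = round(tau / dt), C = C)
}

# analytic single-fish reversal: circulates anticlockwise, reverses at a
# scripted frame with a linear heading sweep, then circulates clockwise
reversal_track <- function(id = "1", n = 1000, rev_frame = 500,
                           sweep_frames = 30, r = 300, v = 130, dt = 0.02) {
  x <- numeric(n); y <- numeric(n)
  x[1] <- r; y[1] <- 0
  for (k in 1:(n - 1)) {
    psi_cur <- atan2(y[k], x[k])
    # small analytic heading oscillation so the raw incidence exceeds its
    # moving average somewhere (thresholds are maxima of the average)
    osc <- 0.06 * sin(2 * pi * k * dt / 0.2)
    s <- if (k < rev_frame) 1 else if (k >= rev_frame + sweep_frames) -1 else NA
    h <- if (is.na(s)) {
      ramp <- (k - rev_frame) / sweep_frames
      psi_cur + pi / 2 - pi * ramp + osc
    } else {
      psi_cur + s * pi / 2 + osc
    }
    x[k + 1] <- x[k] + v * cos(h) * dt
    y[k + 1] <- y[k] + v * sin(h) * dt
  }
  tibble::tibble(frame = 0:(n - 1), time = (0:(n - 1)) * dt, id = id,
                 x = x, y = y)
}

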