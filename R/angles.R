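#' Wrap angles to (-pi, pi]
#'
#' All angular quantities in the package (headings, angular positions,
#' wall-incidence and viewing angles, heading differences) live on the
#' half-open interval (-pi, pi], anticlockwise positive.
#'
#' @param x numeric vector of angles in radians.
#' @return numeric vector of the same length, wrapped to (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% maps pi -> -pi; keep the +pi endpoint instead
  y[!is.na(y) & y == -pi] <- pi
  y
}

#' Smallest signed angular difference a - b
#' @noRd
angle_diff <- function(a, b) wrap_angle(a - b)

#' Von Mises random deviates
#'
#' Best & Fisher (1979) rejection sampler. Used for heading noise in the
#' synthetic-school generator; `kappa = 0` gives the uniform circular
#' distribution.
#'
#' @param n number of deviates.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0); larger is tighter.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(wrap_angle(runif(n, -pi, pi) + mu))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

#' Centered moving average with shrinking windows at the edges
#'
#' Window half-width `h` means a full window of `2h + 1` samples; near the
#' series ends the window truncates rather than padding.
#' @noRd
moving_average <- function(x, window) {
  stopifnot(window >= 1)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  if (n == 0L) return(numeric(0))
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}
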