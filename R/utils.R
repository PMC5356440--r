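#' Evaluate an expression under a fixed RNG seed
#'
#' All stochastic generators in the package funnel their randomness through
#' this helper so that the same `(parameters, seed)` pair always yields the
#' same output without disturbing the caller's RNG state. A `NULL` seed uses
#' (and advances) the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Fold an angle difference into the acute range
#'
#' Orientations of undirected structures (filaments, fibril axes, junction
#' tangents) live on a 180-degree circle; the acute angle between two such
#' axes lies in `[0, 90]` degrees.
#'
#' @param delta_deg Angle difference(s) in degrees (any real value).
#' @return Angle(s) folded into `[0, 90]` degrees.
#' @export
#' @examples
#' fold_acute(170 - 10) # 20
#' fold_acute(c(0, 90, 135, 180, 270))
fold_acute <- function(delta_deg) {
  d <- abs(delta_deg) %% 180
  pmin(d, 180 - d)
}

#' Fold an orientation into [0, 180)
#' @param angle_deg Orientation(s) in degrees.
#' @return Orientation(s) in `[0, 180)`.
#' @export
fold_axial <- function(angle_deg) {
  angle_deg %% 180
}

# difference of two segment directions folded to [0, 180]: used by the
# bend-splitting rule, which treats direction (not axis) as meaningful.
direction_diff <- function(a_deg, b_deg) {
  d <- abs(a_deg - b_deg) %% 360
  pmin(d, 360 - d)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1 || any(!is.finite(x)) || any(x <= 0)) {
    stop_invalid("`", name, "` must be positive and finite")
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_invalid("`", name, "` must be non-negative and finite")
  }
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop_invalid("`", name, "` must be a probability in [0, 1]")
  }
  invisible(x)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler. Used by the filament generator to draw
#' approach angles with controllable concentration; `kappa = 0` reduces to
#' the uniform distribution on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration parameter (>= 0; capped at 1e6).
#' @return `n` draws in `(-pi, pi]` (plus `mu`).
#' @keywords internal
rvonmises <- function(n, mu = 0, kappa = 0) {
  check_nonneg(kappa, "kappa")
  kappa <- min(kappa, 1e6)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    f <- f[ok]; u3 <- u3[ok]
    k <- length(f)
    if (k > 0) {
      out[(got + 1):(got + k)] <- sign(u3 - 0.5) * acos(pmax(-1, pmin(1, f)))
      got <- got + k
    }
  }
  out + mu
}
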