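# Quintic Hermite segments: position, velocity and acceleration prescribed at
# both ends. Used for all joint-angle and root trajectories so that generated
# kinematics are C2-continuous everywhere (differentiable twice, as inverse
# dynamics requires).

#' Quintic polynomial through full end conditions
#'
#' Returns coefficients `c0..c5` of `p(t) = sum c_k t^k` on `[0, duration]`
#' with `p, p', p''` prescribed at both ends.
#'
#' @param p0,v0,a0 position, velocity, acceleration at `t = 0`
#' @param p1,v1,a1 position, velocity, acceleration at `t = duration`
#' @param duration segment length in seconds (> 0)
#' @return numeric vector of 6 polynomial coefficients
#' @keywords internal
quintic_coefs <- function(p0, v0, a0, p1, v1, a1, duration) {
  stopifnot(is.finite(duration), duration > 0)
  T <- duration
  # c0..c2 from the left end; solve 3x3 for c3..c5
  A <- rbind(
    c(T^3,      T^4,       T^5),
    c(3 * T^2,  4 * T^3,   5 * T^4),
    c(6 * T,   12 * T^2,  20 * T^3)
  )
  b <- c(
    p1 - (p0 + v0 * T + a0 / 2 * T^2),
    v1 - (v0 + a0 * T),
    a1 - a0
  )
  c(p0, v0, a0 / 2, solve(A, b))
}

#' Evaluate a polynomial (or derivative) given its coefficients
#' @param coefs coefficients `c0..cK` of `sum c_k t^k`
#' @param t evaluation times
#' @param deriv derivative order (0, 1 or 2)
#' @keywords internal
poly_eval <- function(coefs, t, deriv = 0) {
  k <- seq_along(coefs) - 1
  if (deriv == 1) {
    coefs <- coefs[-1] * k[-1]
  } else if (deriv == 2) {
    if (length(coefs) < 3) return(rep(0, length(t)))
    coefs <- coefs[-(1:2)] * k[-(1:2)] * (k[-(1:2)] - 1)
  } else if (deriv != 0) {
    stop("deriv must be 0, 1 or 2")
  }
  out <- rep(0, length(t))
  for (i in rev(seq_along(coefs))) out <- out * t + coefs[i]
  out
}

# Smoothstep (quintic, zero first/second derivative at both ends), u in [0,1].
smoothstep5 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

#' Septic polynomial through full end conditions including jerk
#'
#' Coefficients `c0..c7` of `p(t) = sum c_k t^k` on `[0, duration]` with
#' `p, p', p'', p'''` prescribed at both ends. Used where C3 continuity
#' keeps trajectory content well below the analysis filter cutoff.
#'
#' @param p0,v0,a0,j0 position, velocity, acceleration, jerk at `t = 0`
#' @param p1,v1,a1,j1 the same at `t = duration`
#' @param duration segment length in seconds (> 0)
#' @return numeric vector of 8 polynomial coefficients
#' @keywords internal
septic_coefs <- function(p0, v0, a0, j0, p1, v1, a1, j1, duration) {
  stopifnot(is.finite(duration), duration > 0)
  T <- duration
  A <- rbind(
    c(T^4,       T^5,       T^6,        T^7),
    c(4 * T^3,   5 * T^4,   6 * T^5,    7 * T^6),
    c(12 * T^2, 20 * T^3,  30 * T^4,   42 * T^5),
    c(24 * T,   60 * T^2, 120 * T^3,  210 * T^4)
  )
  b <- c(
    p1 - (p0 + v0 * T + a0 / 2 * T^2 + j0 / 6 * T^3),
    v1 - (v0 + a0 * T + j0 / 2 * T^2),
    a1 - (a0 + j0 * T),
    j1 - j0
  )
  c(p0, v0, a0 / 2, j0 / 6, solve(A, b))
}
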