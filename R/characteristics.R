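#' Time-resolved TCP by the final-value method of characteristics
#'
#' The TCP is the value of the joint PGF at the origin, TCP(t) = V(0, 0, t).
#' Along the characteristic curves of the PGF PDE the solution is constant,
#' so V(0, 0, t*) can be read off the characteristic that reaches (0, 0) at
#' time t*: solve the characteristic ODEs backward from the final value
#' (0, 0) at t* down to time 0, then apply the PDE's initial condition
#' V(a, q, 0) = a^n_a0 q^n_q0 at the landing point. Reversing the time
#' variable (t -> t* - t) turns this final-value problem into an initial
#' value problem du/dtau = (F_a(u), F_q(u)) with u(0) = (0, 0).
#'
#' For constant (autonomous) death rates the reversed system is the same for
#' every t*, so a single integration yields the whole curve:
#' TCP(t) = u_a(t)^n_a0 * u_q(t)^n_q0. This is
#' [tcp_curve_characteristics()]. For time-dependent death rates the
#' reversed field depends on t* and one backward solve per evaluation time
#' is required: [tcp_at_time()].
#'
#' The characteristic state is a pair of probabilities and must stay inside
#' the unit square; the integrators enforce this to within 1e-9 and abort
#' otherwise. TCP values are assembled as exp(n_a0 log u_a + n_q0 log u_q)
#' to avoid underflow at large initial populations.
#'
#' @param params A [two_compartment_params] object (constant rates for
#'   `tcp_curve_characteristics`; possibly time-dependent for
#'   `tcp_at_time`).
#' @param n_a0,n_q0 Initial numbers of active and quiescent cells.
#' @param times Nonnegative, strictly increasing evaluation grid (days).
#' @param rtol,atol Integrator tolerances. The characteristic state is later
#'   raised to the power of the initial cell count, so it is integrated with
#'   roughly two more digits than the TCP needs.
#' @return `tcp_curve_characteristics`: a [tcp_curve]; `tcp_at_time`: a
#'   single probability.
#' @examples
#' p <- two_compartment_params(0.065, 0.047, f = 0, Gamma_a = 1.5, Gamma_q = 0.4)
#' cv <- tcp_curve_characteristics(p, 100, 100, seq(0, 24, by = 0.5))
#' @name characteristics
NULL

#' @rdname characteristics
#' @export
tcp_curve_characteristics <- function(params, n_a0, n_q0, times,
                                      rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "two_compartment_params"),
            n_a0 >= 0, n_q0 >= 0, all(times >= 0), all(diff(times) > 0))
  if (!has_constant_rates(params)) {
    stop("constant death rates required; use tcp_at_time() for ",
         "time-dependent rates")
  }
  grid <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::ode(
    y = c(a = 0, q = 0), times = grid,
    func = function(tau, u, p) {
      list(unname(pgf_vector_field(u[["a"]], u[["q"]], params)))
    },
    parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  u <- sol[, c("a", "q"), drop = FALSE]
  u <- check_unit_square(u)
  if (times[1] > 0) u <- u[-1L, , drop = FALSE]
  tcp_curve(times, tcp_from_u(u[, "a"], u[, "q"], n_a0, n_q0),
            method = "characteristics")
}

#' @rdname characteristics
#' @param t_star Evaluation time (days) for the per-time final-value solve.
#' @export
tcp_at_time <- function(params, t_star, n_a0, n_q0,
                        rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "two_compartment_params"),
            t_star >= 0, n_a0 >= 0, n_q0 >= 0)
  if (t_star == 0) return(tcp_from_u(0, 0, n_a0, n_q0))
  sol <- deSolve::ode(
    y = c(a = 0, q = 0), times = c(0, t_star),
    func = function(tau, u, p) {
      # reversed clock: tau = t* - t, so rates are evaluated at t* - tau
      # (clamped: the adaptive integrator may probe slightly outside [0, t*])
      list(unname(pgf_vector_field(u[["a"]], u[["q"]], params,
                                   t = min(max(t_star - tau, 0), t_star))))
    },
    parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  u <- check_unit_square(sol[, c("a", "q"), drop = FALSE])
  tcp_from_u(u[2, "a"], u[2, "q"], n_a0, n_q0)
}

# TCP = u_a^n_a0 * u_q^n_q0 in log space, with 0^0 = 1 and u = 0 -> 0
tcp_from_u <- function(ua, uq, n_a0, n_q0) {
  la <- if (n_a0 == 0) 0 else n_a0 * log(pmax(ua, 0))
  lq <- if (n_q0 == 0) 0 else n_q0 * log(pmax(uq, 0))
  out <- exp(la + lq)
  out[!is.finite(la + lq)] <- 0
  unname(pmin(out, 1))
}

# probabilistic interpretation of PGF arguments: abort if the characteristic
# state leaves the unit square beyond tolerance, clamp rounding noise
check_unit_square <- function(u, tol = 1e-9) {
  if (any(u < -tol) || any(u > 1 + tol)) {
    stop("characteristic state left the unit square [0,1]^2 (max excess ",
         format(max(pmax(-u, u - 1))), "); integration is unreliable")
  }
  pmin(pmax(u, 0), 1)
}

#' First time the TCP curve reaches a target level
#'
#' Convenience wrapper around [tcp_curve_characteristics()]: returns the
#' first grid time at which TCP(t) >= `level`.
#'
#' @inheritParams characteristics
#' @param level Target probability (default 0.99).
#' @return The first crossing time in days, or `NA` if the level is not
#'   reached on the grid.
#' @export
time_to_control <- function(params, n_a0, n_q0, times, level = 0.99) {
  cv <- tcp_curve_characteristics(params, n_a0, n_q0, times)
  hit <- which(cv$tcp >= level)
  if (length(hit) == 0) return(NA_real_)
  cv$times[hit[1]]
}
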