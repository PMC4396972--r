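#' Parameters of the two-compartment active/quiescent model
#'
#' The tumor is modelled as a continuous-time Markov branching process with
#' two cell types: active (proliferating) cells A and quiescent (G0) cells Q.
#' An active cell divides at rate `mu`; each of the two daughters is
#' independently active with probability `f` and quiescent with probability
#' `1 - f` (the dividing mother is replaced by its daughters). A quiescent
#' cell re-enters the cycle (Q -> A) at rate `gamma`. Cells die at per-capita
#' rates `Gamma_a` (active) and `Gamma_q` (quiescent), which may be constants
#' or functions of time — e.g. radiation hazards derived from a
#' [dose_protocol] via [hazard()].
#'
#' `f = 1` collapses the model to a one-compartment birth-death process (the
#' Zaider-Minerbo limit); `f = 0` is the fully asymmetric model in which both
#' daughters are born quiescent.
#'
#' @param mu Division rate of active cells (day^-1), nonnegative.
#' @param gamma Quiescent-to-active conversion rate (day^-1), nonnegative.
#' @param f Asymmetric division factor in \[0, 1\]: probability that a
#'   daughter cell is active.
#' @param Gamma_a,Gamma_q Death rates (day^-1): a single nonnegative number,
#'   or a function of time returning a nonnegative rate.
#' @return An object of class `two_compartment_params`.
#' @examples
#' # clinical parameter set at a constant 2.75 Gy/day dose rate
#' p <- two_compartment_params(mu = 0.065, gamma = 0.047, f = 0,
#'                             Gamma_a = 1.5, Gamma_q = 0.4)
#' @export
two_compartment_params <- function(mu, gamma, f, Gamma_a, Gamma_q) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(f), length(f) == 1L, is.finite(f))
  if (mu < 0) stop("'mu' must be nonnegative")
  if (gamma < 0) stop("'gamma' must be nonnegative")
  if (f < 0 || f > 1) stop("'f' must lie in [0, 1]")
  check_rate <- function(g, name) {
    if (is.function(g)) return(g)
    stopifnot(is.numeric(g), length(g) == 1L, is.finite(g))
    if (g < 0) stop(sprintf("'%s' must be nonnegative", name))
    g
  }
  structure(list(mu = mu, gamma = gamma, f = f,
                 Gamma_a = check_rate(Gamma_a, "Gamma_a"),
                 Gamma_q = check_rate(Gamma_q, "Gamma_q")),
            class = "two_compartment_params")
}

#' @export
print.two_compartment_params <- function(x, ...) {
  fmt <- function(g) if (is.function(g)) "time-dependent" else sprintf("%g/day", g)
  cat("Two-compartment active/quiescent model\n")
  cat(sprintf("  mu = %g/day, gamma = %g/day, f = %g\n", x$mu, x$gamma, x$f))
  cat(sprintf("  Gamma_a = %s, Gamma_q = %s\n", fmt(x$Gamma_a), fmt(x$Gamma_q)))
  invisible(x)
}

#' Are both death rates constant in time?
#' @param params A [two_compartment_params] object.
#' @return Logical scalar.
#' @export
has_constant_rates <- function(params) {
  !is.function(params$Gamma_a) && !is.function(params$Gamma_q)
}

#' Death rates at a given time
#'
#' @param params A [two_compartment_params] object.
#' @param t Time in days.
#' @return Named numeric vector `c(Gamma_a = ..., Gamma_q = ...)`.
#' @export
death_rates_at <- function(params, t) {
  ga <- if (is.function(params$Gamma_a)) params$Gamma_a(t) else params$Gamma_a
  gq <- if (is.function(params$Gamma_q)) params$Gamma_q(t) else params$Gamma_q
  c(Gamma_a = ga, Gamma_q = gq)
}

#' Offspring generating function of a division
#'
#' A dividing active cell produces two daughters, each independently active
#' with probability `f`. The offspring probability generating function at the
#' point (a, q) is therefore (f*a + (1-f)*q)^2, i.e. outcomes AA, AQ, QQ with
#' weights f^2, 2f(1-f), (1-f)^2.
#'
#' @param a,q PGF arguments (the evaluation domain of interest is the unit
#'   square).
#' @param f Asymmetric division factor in \[0, 1\].
#' @return The offspring PGF value, vectorized over `a`, `q`.
#' @export
division_pgf <- function(a, q, f) {
  if (any(f < 0 | f > 1)) stop("'f' must lie in [0, 1]")
  (f * a + (1 - f) * q)^2
}

#' Coefficient functions of the generating-function PDE
#'
#' The joint PGF V(a, q, t) of the cell counts satisfies the first-order PDE
#' dV/dt = F_a(a, q, t) dV/da + F_q(a, q, t) dV/dq with
#' \deqn{F_a = \mu[(f a + (1-f) q)^2 - a] + \Gamma_a (1 - a)}
#' \deqn{F_q = \gamma (a - q) + \Gamma_q (1 - q)}
#' Both coefficients vanish at (1, 1), which enforces the normalization
#' V(1, 1, t) = 1.
#'
#' @param a,q PGF arguments (scalars).
#' @param params A [two_compartment_params] object.
#' @param t Time in days (only relevant for time-dependent death rates).
#' @return Named numeric vector `c(F_a = ..., F_q = ...)`.
#' @export
pgf_vector_field <- function(a, q, params, t = 0) {
  g <- death_rates_at(params, t)
  F_a <- params$mu * (division_pgf(a, q, params$f) - a) + g[["Gamma_a"]] * (1 - a)
  F_q <- params$gamma * (a - q) + g[["Gamma_q"]] * (1 - q)
  c(F_a = F_a, F_q = F_q)
}

#' Mean-field (expected-value) dynamics
#'
#' The expectations of the cell counts in the branching process satisfy the
#' linear ODE system
#' \deqn{dn_a/dt = (2f - 1)\mu n_a + \gamma n_q - \Gamma_a n_a}
#' \deqn{dn_q/dt = 2(1-f)\mu n_a - \gamma n_q - \Gamma_q n_q}
#' (a division removes the mother and adds on average 2f active and 2(1-f)
#' quiescent daughters).
#'
#' @param state Numeric vector `c(n_a, n_q)` of (real-valued) populations.
#' @param params A [two_compartment_params] object.
#' @param t Time in days.
#' @return Numeric vector of time derivatives `c(dn_a, dn_q)`.
#' @export
mean_field_rhs <- function(state, params, t = 0) {
  M <- mean_field_matrix(params, t)
  as.numeric(M %*% state)
}

#' Mean-field rate matrix
#'
#' The matrix M of the linear system d(n_a, n_q)/dt = M (n_a, n_q). Its
#' leading eigenvalue determines criticality: positive means supercritical
#' growth (extinction not certain, TCP_inf < 1), negative means subcritical
#' decay (extinction certain, TCP_inf = 1).
#'
#' @inheritParams mean_field_rhs
#' @return A 2x2 numeric matrix.
#' @export
mean_field_matrix <- function(params, t = 0) {
  g <- death_rates_at(params, t)
  matrix(c((2 * params$f - 1) * params$mu - g[["Gamma_a"]], params$gamma,
           2 * (1 - params$f) * params$mu, -(params$gamma + g[["Gamma_q"]])),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("n_a", "n_q"), c("n_a", "n_q")))
}

#' Solve the mean-field ODEs
#'
#' @inheritParams mean_field_rhs
#' @param n_a0,n_q0 Initial populations (nonnegative).
#' @param times Increasing time grid (days) starting at 0.
#' @return A data.frame with columns `time`, `n_a`, `n_q`.
#' @export
mean_field_solution <- function(params, n_a0, n_q0, times) {
  stopifnot(n_a0 >= 0, n_q0 >= 0)
  sol <- deSolve::ode(
    y = c(n_a = n_a0, n_q = n_q0), times = times,
    func = function(t, y, p) list(mean_field_rhs(y, params, t)),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  as.data.frame(sol)
}
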