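#' One-compartment Zaider-Minerbo TCP
#'
#' The classical one-compartment birth-death TCP: cells divide at rate
#' `lambda` and die at rate zeta(t) = `zeta0` + h(t), where h(t) is the
#' radiation hazard of a dose protocol under the LQ model (see [hazard()]).
#' The extinction probability of this process has the closed form
#' \deqn{TCP(t) = \left[1 - \frac{S(t)e^{(\lambda-\zeta_0)t}}
#'   {1 + \lambda S(t)e^{(\lambda-\zeta_0)t}\int_0^t
#'   \frac{du}{S(u)e^{(\lambda-\zeta_0)u}}}\right]^{n_0}}
#' with S(t) the radiation survival probability of [survival_S()]. It is the
#' `f = 1` limit of the two-compartment model (all daughters active), used
#' throughout the package as an independent reference.
#'
#' @param lambda Birth (division) rate, day^-1.
#' @param zeta0 Background (radiation-free) death rate, day^-1.
#' @param n0 Initial number of tumor cells.
#' @param protocol Optional [dose_protocol]; omitted or zero means no
#'   irradiation.
#' @param rs [radiosensitivity] parameters; required with a non-zero
#'   protocol.
#' @return `zm_params` returns an object of class `zm_params`.
#' @examples
#' zp <- zm_params(lambda = 0.065, zeta0 = 1.5, n0 = 100)
#' zm_tcp(zp, c(0, 6, 12, 24))
#' @export
zm_params <- function(lambda, zeta0, n0, protocol = NULL, rs = NULL) {
  stopifnot(is.numeric(lambda), lambda >= 0, is.numeric(zeta0), zeta0 >= 0,
            n0 >= 0)
  if (is.null(protocol)) protocol <- dose_protocol_zero()
  stopifnot(inherits(protocol, "dose_protocol"))
  if (protocol$kind != "zero" && is.null(rs)) {
    stop("radiosensitivity parameters are required with a non-zero protocol")
  }
  structure(list(lambda = lambda, zeta0 = zeta0, n0 = n0,
                 protocol = protocol, rs = rs),
            class = "zm_params")
}

#' @export
print.zm_params <- function(x, ...) {
  cat(sprintf(
    "Zaider-Minerbo model: lambda = %g/day, zeta0 = %g/day, n0 = %g\n",
    x$lambda, x$zeta0, x$n0))
  print(x$protocol)
  invisible(x)
}

#' @rdname zm_params
#' @param zp A `zm_params` object.
#' @param t Evaluation time(s) in days, nonnegative.
#' @return `zm_tcp` returns TCP value(s) in \[0, 1\].
#' @export
zm_tcp <- function(zp, t) {
  stopifnot(inherits(zp, "zm_params"), all(t >= 0))
  vapply(t, function(ti) zm_tcp_one(zp, ti), numeric(1))
}

zm_tcp_one <- function(zp, t) {
  if (zp$n0 == 0) return(1)
  if (t == 0) return(0)
  delta <- zp$lambda - zp$zeta0
  # inv_E(u) = 1 / (S(u) exp(delta u)); TCP per cell = 1 - 1/(inv_E(t) +
  # lambda * integral of inv_E), a form stable for strongly subcritical decay
  if (zp$protocol$kind == "zero") {
    inv_Et <- exp(-delta * t)
    J <- if (abs(delta) < 1e-14) t else (1 - exp(-delta * t)) / delta
  } else {
    inv_E <- function(u) exp(-delta * u) / survival_S(zp$protocol, zp$rs, u)
    inv_Et <- inv_E(t)
    J <- stats::integrate(function(u) vapply(u, inv_E, numeric(1)),
                          0, t, rel.tol = 1e-10, abs.tol = 1e-10,
                          subdivisions = 500L)$value
  }
  denom <- inv_Et + zp$lambda * J
  base <- if (!is.finite(denom)) 1 else 1 - 1 / denom
  tcp_from_u(base, 1, zp$n0, 0)
}
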