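#' Radiosensitivity parameters of the linear-quadratic model
#'
#' Bundles the linear (`alpha`, per Gy) and quadratic (`beta`, per Gy^2)
#' sensitivity coefficients of the linear-quadratic (LQ) cell-survival model.
#' Active (proliferating) and quiescent (G0) cells are typically assigned
#' different values; the clinical set used throughout the package examples is
#' `alpha_a = 0.487`, `alpha_q = 0.155` Gy^-1 and `beta = 0.055` Gy^-2 for
#' both compartments.
#'
#' @param alpha Linear sensitivity coefficient (Gy^-1), nonnegative.
#' @param beta Quadratic sensitivity coefficient (Gy^-2), nonnegative.
#' @return An object of class `radiosensitivity`.
#' @examples
#' rs_active <- radiosensitivity(alpha = 0.487, beta = 0.055)
#' lq_survival(2, rs_active)
#' @export
radiosensitivity <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha < 0 || beta < 0) {
    stop("radiosensitivity parameters 'alpha' and 'beta' must be nonnegative")
  }
  structure(list(alpha = alpha, beta = beta), class = "radiosensitivity")
}

#' @export
print.radiosensitivity <- function(x, ...) {
  cat(sprintf("LQ radiosensitivity: alpha = %g Gy^-1, beta = %g Gy^-2\n",
              x$alpha, x$beta))
  invisible(x)
}

#' Dose-delivery protocols
#'
#' A dose protocol describes the cumulative dose D(t) (Gy) delivered up to
#' time t (days) and its rate dD/dt (Gy/day). Three kinds are supported:
#' no irradiation (`dose_protocol_zero`), a constant dose rate
#' (`dose_protocol_constant`), and a fractionated schedule given as
#' non-overlapping delivery windows each with a start time, duration and
#' fraction dose (`dose_protocol_fractionated`).
#'
#' @param rate Constant dose rate in Gy/day (nonnegative).
#' @param fractions Numeric matrix (or coercible data.frame) with columns
#'   `start` (days), `duration` (days, > 0) and `dose` (Gy, nonnegative);
#'   delivery windows must not overlap. Dose is delivered at constant rate
#'   `dose/duration` within each window.
#' @return An object of class `dose_protocol`.
#' @examples
#' p <- dose_protocol_constant(2.75)
#' cumulative_dose(p, c(0, 1, 2))
#' @name dose_protocol
NULL

#' @rdname dose_protocol
#' @export
dose_protocol_zero <- function() {
  structure(list(kind = "zero"), class = "dose_protocol")
}

#' @rdname dose_protocol
#' @export
dose_protocol_constant <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate))
  if (rate < 0) stop("dose rate must be nonnegative")
  structure(list(kind = "constant", rate = rate), class = "dose_protocol")
}

#' @rdname dose_protocol
#' @export
dose_protocol_fractionated <- function(fractions) {
  fr <- as.matrix(fractions)
  if (ncol(fr) != 3L) stop("'fractions' needs columns start, duration, dose")
  colnames(fr) <- c("start", "duration", "dose")
  storage.mode(fr) <- "double"
  if (any(!is.finite(fr))) stop("fraction entries must be finite")
  if (any(fr[, "start"] < 0)) stop("fraction start times must be nonnegative")
  if (any(fr[, "duration"] <= 0)) stop("fraction durations must be positive")
  if (any(fr[, "dose"] < 0)) stop("fraction doses must be nonnegative")
  fr <- fr[order(fr[, "start"]), , drop = FALSE]
  ends <- fr[, "start"] + fr[, "duration"]
  if (nrow(fr) > 1L && any(fr[-1L, "start"] < ends[-nrow(fr)] - 1e-12)) {
    stop("fraction intervals must not overlap")
  }
  structure(list(kind = "fractionated", fractions = fr),
            class = "dose_protocol")
}

#' @export
print.dose_protocol <- function(x, ...) {
  switch(x$kind,
    zero = cat("Dose protocol: no irradiation\n"),
    constant = cat(sprintf("Dose protocol: constant %g Gy/day\n", x$rate)),
    fractionated = {
      cat(sprintf("Dose protocol: %d fraction(s), total %g Gy\n",
                  nrow(x$fractions), sum(x$fractions[, "dose"])))
    })
  invisible(x)
}

#' Cumulative dose and dose rate of a protocol
#'
#' @param protocol A [dose_protocol].
#' @param t Time(s) in days, nonnegative.
#' @return Numeric vector: cumulative dose D(t) in Gy, or instantaneous dose
#'   rate dD/dt in Gy/day.
#' @export
cumulative_dose <- function(protocol, t) {
  stopifnot(inherits(protocol, "dose_protocol"), all(t >= 0))
  switch(protocol$kind,
    zero = rep(0, length(t)),
    constant = protocol$rate * t,
    fractionated = {
      fr <- protocol$fractions
      vapply(t, function(ti) {
        done <- pmin(pmax(ti - fr[, "start"], 0), fr[, "duration"])
        sum(fr[, "dose"] * done / fr[, "duration"])
      }, numeric(1))
    })
}

#' @rdname cumulative_dose
#' @export
dose_rate <- function(protocol, t) {
  stopifnot(inherits(protocol, "dose_protocol"), all(t >= 0))
  switch(protocol$kind,
    zero = rep(0, length(t)),
    constant = rep(protocol$rate, length(t)),
    fractionated = {
      fr <- protocol$fractions
      vapply(t, function(ti) {
        inside <- ti >= fr[, "start"] & ti < fr[, "start"] + fr[, "duration"]
        sum(fr[inside, "dose"] / fr[inside, "duration"])
      }, numeric(1))
    })
}

#' Linear-quadratic survival fraction
#'
#' Surviving fraction exp(-alpha*D - beta*D^2) of cells exposed to a total
#' dose D.
#'
#' @param D Total dose in Gy (nonnegative, vectorized).
#' @param rs A [radiosensitivity] object.
#' @return Survival fraction(s) in \[0, 1\].
#' @export
lq_survival <- function(D, rs) {
  stopifnot(inherits(rs, "radiosensitivity"))
  if (any(D < 0)) stop("dose must be nonnegative")
  exp(-rs$alpha * D - rs$beta * D^2)
}

#' Radiation hazard function
#'
#' Instantaneous per-cell kill rate h(t) implied by the LQ model under a
#' dose protocol: h(t) = (alpha + 2 beta D(t)) dD/dt, the negative
#' log-derivative of the LQ survival along the cumulative dose. Zero whenever
#' the beam is off.
#'
#' @inheritParams cumulative_dose
#' @param rs A [radiosensitivity] object.
#' @return Hazard(s) in day^-1, nonnegative.
#' @export
hazard <- function(protocol, rs, t) {
  stopifnot(inherits(rs, "radiosensitivity"))
  (rs$alpha + 2 * rs$beta * cumulative_dose(protocol, t)) *
    dose_rate(protocol, t)
}

#' Radiation survival probability S(t)
#'
#' S(t) = exp(-integral of the hazard from 0 to t). For a constant-rate
#' protocol the cumulative hazard has the closed form alpha*r*t +
#' beta*(r*t)^2; otherwise the integral is evaluated by adaptive quadrature
#' split at beam-on/off boundaries (absolute tolerance 1e-10).
#'
#' @inheritParams hazard
#' @return Survival probabilities in \[0, 1\], nonincreasing in `t`.
#' @export
survival_S <- function(protocol, rs, t) {
  stopifnot(inherits(rs, "radiosensitivity"), all(t >= 0))
  switch(protocol$kind,
    zero = rep(1, length(t)),
    constant = {
      D <- protocol$rate * t
      exp(-(rs$alpha * D + rs$beta * D^2))
    },
    fractionated = vapply(t, function(ti) {
      exp(-cumulative_hazard_quad(protocol, rs, ti))
    }, numeric(1)))
}

#' Hazard-derived time-dependent death rate
#'
#' Packages the radiation hazard of a protocol, plus an optional background
#' rate, as a function of time suitable for the `Gamma_a` / `Gamma_q` slots
#' of [two_compartment_params()]. This is the general (time-dependent) way
#' to couple a dose schedule to the two-compartment model; the constant
#' effective rates used in the package's reference experiments are the
#' simpler alternative.
#'
#' @inheritParams hazard
#' @param background Constant radiation-free death rate (day^-1).
#' @return A function `function(t)` returning the total death rate.
#' @export
death_rate_from_protocol <- function(protocol, rs, background = 0) {
  stopifnot(background >= 0)
  force(protocol); force(rs)
  function(t) background + hazard(protocol, rs, t)
}

# Adaptive quadrature of the hazard on [0, t], split at window edges so the
# integrand is smooth on every subinterval.
cumulative_hazard_quad <- function(protocol, rs, t) {
  if (t == 0) return(0)
  edges <- c(0, t)
  if (protocol$kind == "fractionated") {
    fr <- protocol$fractions
    edges <- c(edges, fr[, "start"], fr[, "start"] + fr[, "duration"])
  }
  edges <- sort(unique(pmin(pmax(edges, 0), t)))
  total <- 0
  for (i in seq_len(length(edges) - 1L)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    if (hi - lo < 1e-14) next
    total <- total + stats::integrate(function(u) hazard(protocol, rs, u),
                                      lo, hi, abs.tol = 1e-10,
                                      rel.tol = 1e-10)$value
  }
  total
}
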