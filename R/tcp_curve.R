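#' TCP curve container
#'
#' A time grid together with tumor control probabilities, the method that
#' produced them, and (for Monte-Carlo estimates) exact binomial 95%
#' confidence bounds.
#'
#' @param times Nonnegative, strictly increasing time grid (days).
#' @param tcp Probabilities in \[0, 1\], one per time point.
#' @param method One of `"characteristics"`, `"gillespie"`,
#'   `"zaider-minerbo"`.
#' @param ci_low,ci_high Optional confidence bounds (Gillespie only).
#' @return An object of class `tcp_curve`.
#' @export
tcp_curve <- function(times, tcp, method, ci_low = NULL, ci_high = NULL) {
  stopifnot(is.numeric(times), is.numeric(tcp), length(times) == length(tcp),
            all(diff(times) > 0), all(times >= 0))
  method <- match.arg(method, c("characteristics", "gillespie", "zaider-minerbo"))
  if (any(tcp < -1e-9 | tcp > 1 + 1e-9)) {
    stop("TCP values fall outside [0, 1] beyond numerical tolerance")
  }
  tcp <- pmin(pmax(tcp, 0), 1)
  structure(list(times = times, tcp = tcp, method = method,
                 ci_low = ci_low, ci_high = ci_high),
            class = "tcp_curve")
}

#' @export
print.tcp_curve <- function(x, ...) {
  cat(sprintf("TCP curve (%s): %d time points over [%g, %g] days\n",
              x$method, length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  TCP range: [%.4g, %.4g]\n", min(x$tcp), max(x$tcp)))
  invisible(x)
}

#' @export
as.data.frame.tcp_curve <- function(x, ...) {
  out <- data.frame(t_days = x$times, tcp = x$tcp)
  if (!is.null(x$ci_low)) {
    out$ci_low <- x$ci_low
    out$ci_high <- x$ci_high
  }
  out
}

#' Interpolate a TCP curve at arbitrary times
#'
#' Linear interpolation within the stored grid (constant extrapolation at
#' the ends, which is exact for a Gillespie step estimate sampled at grid
#' times).
#'
#' @param curve A [tcp_curve].
#' @param t Times (days) at which to evaluate.
#' @return Numeric vector of TCP values.
#' @export
tcp_at <- function(curve, t) {
  stopifnot(inherits(curve, "tcp_curve"))
  stats::approx(curve$times, curve$tcp, xout = t, rule = 2)$y
}
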