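#' Fixed points of the generating-function PDE
#'
#' Stationary points (a*, q*) of the characteristic vector field
#' (F_a, F_q) of the PGF PDE (see [pgf_vector_field()]), for constant death
#' rates. The point (1, 1) is always a fixed point. Setting F_q = 0 gives
#' a = ((gamma + Gamma_q) q - Gamma_q) / gamma, linear in q; substituting
#' into F_a = 0 yields a quadratic c1 q^2 + c2 q + c3 = 0 whose real roots,
#' mapped back through the linear relation, are the fixed points. Every
#' reported root is verified to satisfy both stationarity conditions to a
#' residual below 1e-10.
#'
#' When `gamma = 0` the elimination is degenerate (the quiescent equation no
#' longer couples a to q); the quiescent coordinate is then resolved
#' directly — q* = 1 when Gamma_q > 0 (an isolated quiescent lineage dies
#' out surely), q* = 0 when Gamma_q = 0 (it never goes extinct) — and the
#' active coordinate solves the remaining quadratic in a.
#'
#' @param params A [two_compartment_params] object with constant rates.
#' @return An object of class `fixed_point_result`: a list with elements
#'   `trivial` (the point (1,1)), `nontrivial` (list of real roots
#'   `c(a, q)`), `coefficients` (c1, c2, c3; `NA` on the degenerate
#'   `gamma = 0` path), `regime` (see [classify_regime()]) and `residuals`.
#' @export
fixed_points <- function(params) {
  stopifnot(inherits(params, "two_compartment_params"))
  if (!has_constant_rates(params)) {
    stop("fixed points are defined for constant death rates only")
  }
  mu <- params$mu; gamma <- params$gamma; f <- params$f
  Ga <- params$Gamma_a; Gq <- params$Gamma_q

  roots <- list()
  coefs <- c(c1 = NA_real_, c2 = NA_real_, c3 = NA_real_)

  if (gamma > 0) {
    # a = A1*q + A0 from F_q = 0; s = f*a + (1-f)*q = B1*q + B0
    A1 <- (gamma + Gq) / gamma
    A0 <- -Gq / gamma
    B1 <- f * A1 + (1 - f)
    B0 <- f * A0
    c1 <- mu * B1^2
    c2 <- 2 * mu * B1 * B0 - (mu + Ga) * A1
    c3 <- mu * B0^2 - (mu + Ga) * A0 + Ga
    coefs <- c(c1 = c1, c2 = c2, c3 = c3)
    for (q in quadratic_roots(c1, c2, c3)) {
      roots <- c(roots, list(c(a = A1 * q + A0, q = q)))
    }
  } else {
    # gamma = 0: quiescent dynamics decouple
    q_star <- if (Gq > 0) 1 else 0
    # F_a = 0 with q fixed: mu*f^2 a^2 + (2 mu f (1-f) q - mu - Ga) a
    #                        + mu (1-f)^2 q^2 + Ga = 0
    ca <- mu * f^2
    cb <- 2 * mu * f * (1 - f) * q_star - mu - Ga
    cc <- mu * (1 - f)^2 * q_star^2 + Ga
    for (a in quadratic_roots(ca, cb, cc)) {
      roots <- c(roots, list(c(a = a, q = q_star)))
    }
  }

  # keep roots satisfying both stationarity conditions; drop (1,1) duplicate
  resid <- function(r) max(abs(pgf_vector_field(r[["a"]], r[["q"]], params)))
  keep <- vapply(roots, function(r) resid(r) < 1e-10, logical(1))
  roots <- roots[keep]
  nontrivial <- Filter(function(r) max(abs(r - 1)) > 1e-9, roots)

  structure(list(
    trivial = c(a = 1, q = 1),
    nontrivial = nontrivial,
    coefficients = coefs,
    regime = classify_regime(params),
    residuals = vapply(nontrivial, resid, numeric(1))
  ), class = "fixed_point_result")
}

#' @export
print.fixed_point_result <- function(x, ...) {
  cat("Fixed points of the PGF characteristic field\n")
  cat("  trivial: (1, 1)\n")
  if (length(x$nontrivial) == 0) {
    cat("  nontrivial: none\n")
  } else {
    for (r in x$nontrivial) {
      cat(sprintf("  nontrivial: (a* = %.6g, q* = %.6g)\n", r[["a"]], r[["q"]]))
    }
  }
  cat(sprintf("  regime: %s\n", x$regime))
  invisible(x)
}

# Real roots of c1 x^2 + c2 x + c3 = 0, numerically stable form; handles the
# linear (c1 ~ 0) case.
quadratic_roots <- function(c1, c2, c3) {
  if (abs(c1) < 1e-14) {
    if (abs(c2) < 1e-14) return(numeric(0))
    return(-c3 / c2)
  }
  disc <- c2^2 - 4 * c1 * c3
  if (disc < 0) return(numeric(0))
  sq <- sqrt(disc)
  # Citardauq form avoids cancellation
  u <- -(c2 + sign(c2 + (c2 == 0)) * sq) / 2
  r1 <- u / c1
  r2 <- if (abs(u) > 0) c3 / u else -c2 / c1 - r1
  unique(c(r1, r2))
}

# Nontrivial fixed points strictly inside the unit square [0, 1)^2
minimal_interior_root <- function(fp, tol = 1e-8) {
  inside <- Filter(function(r) {
    all(r >= -tol) && all(r < 1 - tol)
  }, fp$nontrivial)
  if (length(inside) == 0) return(NULL)
  # extinction probability is the componentwise-minimal root
  best <- inside[[1]]
  for (r in inside) if (all(r <= best + tol)) best <- r
  pmin(pmax(best, 0), 1)
}

#' Steady-state tumor control probability
#'
#' The long-time limit of the extinction probability: TCP_inf =
#' (a*)^n_a0 * (q*)^n_q0, where (a*, q*) is the componentwise-minimal fixed
#' point of the PGF characteristic field inside the unit square (the
#' standard minimal-root extinction result for branching processes). When no
#' nontrivial fixed point lies in \[0, 1)^2, the point (1, 1) is globally
#' attractive and the tumor goes extinct with certainty: TCP_inf = 1.
#'
#' @inheritParams fixed_points
#' @param n_a0,n_q0 Initial numbers of active and quiescent cells.
#' @return The steady-state TCP, a probability in \[0, 1\].
#' @examples
#' p <- two_compartment_params(0.065, 0.047, f = 0, Gamma_a = 1.5, Gamma_q = 0.4)
#' tcp_infinity(p, 100, 100)  # 1: clinical rates lie deep in the control phase
#' @export
tcp_infinity <- function(params, n_a0, n_q0) {
  stopifnot(n_a0 >= 0, n_q0 >= 0)
  if (n_a0 + n_q0 == 0) return(1)
  root <- minimal_interior_root(fixed_points(params))
  if (is.null(root)) return(1)
  pow0 <- function(x, n) if (n == 0) 1 else x^n
  pow0(root[["a"]], n_a0) * pow0(root[["q"]], n_q0)
}

#' Leading eigenvalue of the mean-field matrix
#'
#' @inheritParams mean_field_matrix
#' @return The largest real part among the eigenvalues of
#'   [mean_field_matrix()] (both eigenvalues of this Metzler matrix are
#'   real).
#' @export
leading_eigenvalue <- function(params, t = 0) {
  max(Re(eigen(mean_field_matrix(params, t), only.values = TRUE)$values))
}

#' Criticality regime of the model
#'
#' Classifies the parameter set by the sign of the leading eigenvalue of the
#' mean-field matrix: positive means supercritical (the tumor can grow
#' without bound; TCP_inf < 1), negative means subcritical (extinction is
#' certain; TCP_inf = 1), zero means critical. This eigenvalue criterion is
#' independent of — and must always agree with — the fixed-point-location
#' criterion used by [tcp_infinity()].
#'
#' @inheritParams fixed_points
#' @param tol Half-width of the band around zero treated as critical.
#' @return One of `"supercritical"`, `"critical"`, `"subcritical"`.
#' @export
classify_regime <- function(params, tol = 1e-9) {
  lam <- leading_eigenvalue(params)
  if (lam > tol) "supercritical" else if (lam < -tol) "subcritical" else "critical"
}

# Root-bracketing on the leading eigenvalue along one parameter axis.
# make_params(x) must return a two_compartment_params; eigenvalue assumed
# monotone in x on [0, x_max]. Returns the critical x or NA if no sign
# change lies in the bracket.
criticality_root <- function(make_params, x_max) {
  g <- function(x) leading_eigenvalue(make_params(x))
  g0 <- g(0); g1 <- g(x_max)
  if (abs(g0) < 1e-12) return(0)
  if (sign(g0) == sign(g1)) return(NA_real_)
  stats::uniroot(g, c(0, x_max), tol = 1e-12)$root
}

#' Phase boundary in the death-rate plane
#'
#' For each active-cell death rate Gamma_a on a grid, finds the quiescent
#' death rate Gamma_q at which the model is exactly critical (the nontrivial
#' fixed point crosses (1,1)), by root-bracketing on the leading eigenvalue
#' of the mean-field matrix. Grid points for which no critical Gamma_q >= 0
#' exists below `Gamma_q_max` are omitted (with a message when `verbose`).
#'
#' For `f = 0` the boundary meets the axes at Gamma_a = mu (on the Gamma_a
#' axis) and Gamma_q = gamma (on the Gamma_q axis); for `f = 1` quiescent
#' deaths are irrelevant to criticality and the boundary degenerates to the
#' vertical line Gamma_a = mu, so every off-line grid point is omitted.
#'
#' @param mu,gamma Division and conversion rates (day^-1).
#' @param f Asymmetric division factor in \[0, 1\].
#' @param Gamma_a_grid Nonnegative grid of active death rates (day^-1).
#' @param Gamma_q_max Upper bracket for the critical quiescent death rate.
#' @param verbose Emit a message for omitted grid points.
#' @return A data.frame with columns `f`, `Gamma_a`, `Gamma_q` (boundary
#'   points only).
#' @export
phase_boundary_death_rates <- function(mu, gamma, f, Gamma_a_grid,
                                       Gamma_q_max = 100, verbose = FALSE) {
  stopifnot(all(Gamma_a_grid >= 0))
  gq <- vapply(Gamma_a_grid, function(Ga) {
    criticality_root(function(x) {
      two_compartment_params(mu, gamma, f, Gamma_a = Ga, Gamma_q = x)
    }, Gamma_q_max)
  }, numeric(1))
  if (verbose && anyNA(gq)) {
    message(sum(is.na(gq)), " grid point(s) without a critical Gamma_q in [0, ",
            Gamma_q_max, "] omitted")
  }
  keep <- !is.na(gq)
  data.frame(f = rep(f, sum(keep)), Gamma_a = Gamma_a_grid[keep],
             Gamma_q = gq[keep])
}

#' Phase boundary in the division/conversion-rate plane
#'
#' As [phase_boundary_death_rates()] with the roles of the rate pairs
#' exchanged: for each division rate mu on a grid, finds the conversion rate
#' gamma at which the model is exactly critical, holding the death rates
#' fixed. For `f = 1` criticality is independent of gamma and the boundary
#' is the vertical line mu = Gamma_a (off-line grid points omitted).
#'
#' @param Gamma_a,Gamma_q Death rates (day^-1).
#' @param f Asymmetric division factor in \[0, 1\].
#' @param mu_grid Nonnegative grid of division rates (day^-1).
#' @param gamma_max Upper bracket for the critical conversion rate.
#' @param verbose Emit a message for omitted grid points.
#' @return A data.frame with columns `f`, `mu`, `gamma`.
#' @export
phase_boundary_rates <- function(Gamma_a, Gamma_q, f, mu_grid,
                                 gamma_max = 100, verbose = FALSE) {
  stopifnot(all(mu_grid >= 0))
  gam <- vapply(mu_grid, function(mu) {
    criticality_root(function(x) {
      two_compartment_params(mu, gamma = x, f = f,
                             Gamma_a = Gamma_a, Gamma_q = Gamma_q)
    }, gamma_max)
  }, numeric(1))
  if (verbose && anyNA(gam)) {
    message(sum(is.na(gam)), " grid point(s) without a critical gamma in [0, ",
            gamma_max, "] omitted")
  }
  keep <- !is.na(gam)
  data.frame(f = rep(f, sum(keep)), mu = mu_grid[keep], gamma = gam[keep])
}
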