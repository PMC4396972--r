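#' Exact stochastic simulation of the two-compartment model
#'
#' Gillespie's stochastic simulation algorithm over the model's reaction
#' channels: division of an active cell (total propensity mu * n_a, with the
#' daughter pair AA, AQ or QQ drawn with probabilities f^2, 2f(1-f),
#' (1-f)^2), quiescent-to-active conversion (gamma * n_q), active-cell death
#' (Gamma_a * n_a) and quiescent-cell death (Gamma_q * n_q). Waiting times
#' are exponential with rate equal to the total propensity; the channel is
#' selected by an independent uniform draw weighted by the individual
#' propensities. A run terminates when the tumor is extinct
#' (n_a + n_q = 0) or when the clock passes `t_max`.
#'
#' @param params A [two_compartment_params] object with constant death
#'   rates (the SSA is time-homogeneous).
#' @param n_a0,n_q0 Initial cell counts (nonnegative integers).
#' @param t_max Simulation horizon in days (> 0).
#' @return `simulate_run`: the extinction time in days, or `Inf` if the
#'   tumor is not extinct by `t_max`.
#' @export
simulate_run <- function(params, n_a0, n_q0, t_max) {
  stopifnot(inherits(params, "two_compartment_params"),
            n_a0 >= 0, n_q0 >= 0, t_max > 0)
  if (!has_constant_rates(params)) {
    stop("the Gillespie simulator requires constant death rates")
  }
  mu <- params$mu; gamma <- params$gamma
  Ga <- params$Gamma_a; Gq <- params$Gamma_q
  f <- params$f
  p_aa <- f * f
  p_aa_aq <- f * f + 2 * f * (1 - f)
  na <- as.integer(n_a0); nq <- as.integer(n_q0)
  t <- 0
  repeat {
    if (na + nq == 0L) return(t)
    r_div <- mu * na
    r_con <- gamma * nq
    r_da <- Ga * na
    r_dq <- Gq * nq
    total <- r_div + r_con + r_da + r_dq
    if (total <= 0) return(Inf)               # absorbing nonempty state
    t <- t + stats::rexp(1L, total)
    if (t > t_max) return(Inf)
    u <- stats::runif(1L) * total
    if (u < r_div) {
      v <- stats::runif(1L)
      if (v < p_aa) {
        na <- na + 1L                          # A -> A + A
      } else if (v < p_aa_aq) {
        nq <- nq + 1L                          # A -> A + Q
      } else {
        na <- na - 1L; nq <- nq + 2L           # A -> Q + Q
      }
    } else if (u < r_div + r_con) {
      na <- na + 1L; nq <- nq - 1L             # Q -> A
    } else if (u < r_div + r_con + r_da) {
      na <- na - 1L                            # A -> 0
    } else {
      nq <- nq - 1L                            # Q -> 0
    }
  }
}

#' Population snapshot of a single Gillespie run
#'
#' As [simulate_run()], but returns the cell counts at a fixed observation
#' time instead of the extinction time. Used to compare ensemble means with
#' the mean-field ODE solution, which the expectations of this linear
#' branching process satisfy exactly.
#'
#' @inheritParams simulate_run
#' @param t_obs Observation time (days).
#' @return Named integer vector `c(n_a, n_q)` at `t_obs`.
#' @export
simulate_state <- function(params, n_a0, n_q0, t_obs) {
  stopifnot(inherits(params, "two_compartment_params"),
            n_a0 >= 0, n_q0 >= 0, t_obs >= 0)
  if (!has_constant_rates(params)) {
    stop("the Gillespie simulator requires constant death rates")
  }
  mu <- params$mu; gamma <- params$gamma
  Ga <- params$Gamma_a; Gq <- params$Gamma_q
  f <- params$f
  p_aa <- f * f
  p_aa_aq <- f * f + 2 * f * (1 - f)
  na <- as.integer(n_a0); nq <- as.integer(n_q0)
  t <- 0
  repeat {
    total <- (mu + Ga) * na + (gamma + Gq) * nq
    if (total <= 0) break
    t <- t + stats::rexp(1L, total)
    if (t > t_obs) break
    u <- stats::runif(1L) * total
    r_div <- mu * na; r_con <- gamma * nq; r_da <- Ga * na
    if (u < r_div) {
      v <- stats::runif(1L)
      if (v < p_aa) na <- na + 1L
      else if (v < p_aa_aq) nq <- nq + 1L
      else { na <- na - 1L; nq <- nq + 2L }
    } else if (u < r_div + r_con) {
      na <- na + 1L; nq <- nq - 1L
    } else if (u < r_div + r_con + r_da) {
      na <- na - 1L
    } else {
      nq <- nq - 1L
    }
  }
  c(n_a = na, n_q = nq)
}

#' Ensemble of Gillespie runs
#'
#' Runs `M` independent realizations. Each run draws from its own RNG
#' substream seeded from the master `seed`, so the ensemble is bitwise
#' reproducible and its first k runs do not depend on `M` (an ensemble can
#' be extended, or split across workers, without changing earlier runs).
#'
#' @inheritParams simulate_run
#' @param M Number of runs.
#' @param seed Master integer seed.
#' @return An object of class `simulation_ensemble`: list with
#'   `extinction_times` (`Inf` marks runs not extinct by `t_max`), `M`,
#'   `t_max`, `seed`.
#' @export
simulate_ensemble <- function(params, n_a0, n_q0, t_max, M, seed) {
  stopifnot(M >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, M, replace = TRUE)
  ext <- vapply(seq_len(M), function(i) {
    set.seed(run_seeds[i])
    simulate_run(params, n_a0, n_q0, t_max)
  }, numeric(1))
  structure(list(extinction_times = ext, M = M, t_max = t_max, seed = seed),
            class = "simulation_ensemble")
}

#' @export
print.simulation_ensemble <- function(x, ...) {
  n_ext <- sum(is.finite(x$extinction_times))
  cat(sprintf("Gillespie ensemble: %d runs, horizon %g days, seed %d\n",
              x$M, x$t_max, x$seed))
  cat(sprintf("  extinct by horizon: %d (%.1f%%)\n", n_ext, 100 * n_ext / x$M))
  invisible(x)
}

#' Monte-Carlo TCP estimator
#'
#' TCP(t) is estimated as the fraction of runs whose treatment-success
#' indicator is 1 at time t, i.e. whose extinction time is <= t. Runs still
#' alive at the horizon count as failures at every grid time. Exact
#' (Clopper-Pearson) binomial 95% confidence bounds are attached.
#'
#' @inheritParams simulate_ensemble
#' @param times Strictly increasing evaluation grid (days); the horizon
#'   defaults to its maximum.
#' @return A [tcp_curve] with method `"gillespie"` and confidence bounds.
#' @examples
#' p <- two_compartment_params(0.065, 0.047, f = 0, Gamma_a = 1.5, Gamma_q = 0.4)
#' est <- estimate_tcp(p, 10, 10, times = seq(0, 24, by = 3), M = 200, seed = 1)
#' @export
estimate_tcp <- function(params, n_a0, n_q0, times, M, seed,
                         t_max = max(times)) {
  ens <- simulate_ensemble(params, n_a0, n_q0, t_max, M, seed)
  ext <- ens$extinction_times
  x <- vapply(times, function(t) sum(ext <= t), numeric(1))
  tcp_curve(times, x / M, method = "gillespie",
            ci_low = ifelse(x == 0, 0, stats::qbeta(0.025, x, M - x + 1)),
            ci_high = ifelse(x == M, 1, stats::qbeta(0.975, x + 1, M - x)))
}
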