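# shared fixtures and small independent oracles

# clinical two-compartment parameter set (constant 2.75 Gy/day effective
# death rates); gamma defaults to the literature value used for the
# time-resolved experiments, the phase-boundary caption value is 0.05
clinical_params <- function(f = 0, gamma = 0.047) {
  two_compartment_params(mu = 0.065, gamma = gamma, f = f,
                         Gamma_a = 1.5, Gamma_q = 0.4)
}

# random parameter draw; optionally kept away from the critical manifold
# (|leading eigenvalue| >= eig_min) so regime labels are well defined
random_params <- function(eig_min = 0) {
  repeat {
    p <- two_compartment_params(
      mu = runif(1, 0.05, 1.5), gamma = runif(1, 0.05, 1.5),
      f = runif(1), Gamma_a = runif(1, 0, 1.5), Gamma_q = runif(1, 0, 1.5))
    if (abs(leading_eigenvalue(p)) >= eig_min) return(p)
  }
}

# damped finite-difference Newton search for zeros of the characteristic
# field; independent oracle for fixed-point location
newton_fixed_point <- function(params, start, iters = 200, h = 1e-7) {
  x <- start
  for (i in seq_len(iters)) {
    Fx <- pgf_vector_field(x[1], x[2], params)
    J <- cbind(
      (pgf_vector_field(x[1] + h, x[2], params) - Fx) / h,
      (pgf_vector_field(x[1], x[2] + h, params) - Fx) / h)
    step <- tryCatch(solve(J, Fx), error = function(e) return(NULL))
    if (is.null(step)) return(NULL)
    x <- x - pmin(pmax(step, -0.2), 0.2)
    if (max(abs(Fx)) < 1e-13) break
  }
  if (max(abs(pgf_vector_field(x[1], x[2], params))) < 1e-9) x else NULL
}

# master-equation generator applied to the monomial a^na q^nq: enumerates
# the five reaction channels from state (na, nq); oracle for the PDE
# coefficient functions
generator_on_monomial <- function(a, q, na, nq, params) {
  phi <- function(na, nq) a^na * q^nq
  mu <- params$mu; f <- params$f
  base <- phi(na, nq)
  mu * f^2 * na           * (phi(na + 1, nq) - base) +      # A -> A + A
  mu * 2 * f * (1 - f) * na * (phi(na, nq + 1) - base) +    # A -> A + Q
  mu * (1 - f)^2 * na     * (phi(na - 1, nq + 2) - base) +  # A -> Q + Q
  params$gamma * nq       * (phi(na + 1, nq - 1) - base) +  # Q -> A
  params$Gamma_a * na     * (phi(na - 1, nq) - base) +      # A death
  params$Gamma_q * nq     * (phi(na, nq - 1) - base)        # Q death
}

# write a temporary YAML experiment config from a list
write_config <- function(lst) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(lst, path)
  path
}

valid_config_list <- function() {
  list(model = list(mu = 0.065, gamma = 0.047, f = 0,
                    Gamma_a = 1.5, Gamma_q = 0.4),
       populations = list(n_a0 = 100, n_q0 = 100),
       method = "characteristics",
       times = list(t_max = 24, t_step = 0.5))
}
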