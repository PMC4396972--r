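test_that("TCP is zero at t = 0 for a nonempty tumor", {
  p <- clinical_params()
  cv <- tcp_curve_characteristics(p, 100, 100, c(0, 1))
  expect_equal(cv$tcp[1], 0)
  expect_equal(tcp_at_time(p, 0, 3, 4), 0)
})

test_that("pure-death model matches the closed form", {
  # mu = gamma = 0: independent exponential death times, so
  # TCP(t) = (1 - e^(-Ga t))^na0 * (1 - e^(-Gq t))^nq0
  p <- two_compartment_params(0, 0, 0, Gamma_a = 1.5, Gamma_q = 0.4)
  t <- seq(0, 10, 0.5)
  cv <- tcp_curve_characteristics(p, 7, 4, t)
  expect_equal(cv$tcp, (1 - exp(-1.5 * t))^7 * (1 - exp(-0.4 * t))^4,
               tolerance = 1e-6)
})

test_that("long-time limit equals the steady-state TCP", {
  set.seed(31)
  for (i in 1:10) {
    p <- random_params(eig_min = 0.1)
    horizon <- 30 / abs(leading_eigenvalue(p))
    cv <- tcp_curve_characteristics(p, 4, 3, c(0, horizon))
    expect_equal(cv$tcp[2], tcp_infinity(p, 4, 3), tolerance = 1e-6)
  }
})

test_that("per-time final-value solves agree with the single autonomous solve", {
  p <- clinical_params()
  cv <- tcp_curve_characteristics(p, 100, 100, c(0, 12))
  expect_equal(tcp_at_time(p, 12, 100, 100), cv$tcp[2], tolerance = 1e-8)
})

test_that("f = 1 curve equals the Zaider-Minerbo closed form", {
  p <- two_compartment_params(0.065, 0.047, 1, Gamma_a = 1.5, Gamma_q = 0.4)
  zp <- zm_params(lambda = 0.065, zeta0 = 1.5, n0 = 100)
  t <- seq(0, 24, 1)
  cv <- tcp_curve_characteristics(p, 100, 0, t)
  expect_equal(cv$tcp, zm_tcp(zp, t), tolerance = 1e-6)
})

test_that("time-dependent death rates: final-value solver matches the ZM
           hazard formulation", {
  rs <- radiosensitivity(0.487, 0.055)
  proto <- dose_protocol_constant(1.2)
  Ga <- death_rate_from_protocol(proto, rs, background = 0.15)
  p <- two_compartment_params(0.1, 0.3, 1, Gamma_a = Ga, Gamma_q = 0.2)
  zp <- zm_params(lambda = 0.1, zeta0 = 0.15, n0 = 8,
                  protocol = proto, rs = rs)
  for (t_star in c(1, 3, 6)) {
    expect_equal(tcp_at_time(p, t_star, 8, 0), zm_tcp(zp, t_star),
                 tolerance = 1e-6)
  }
})

test_that("characteristics preserve the PGF normalization at (1,1)", {
  p <- clinical_params(f = 0.4)
  sol <- deSolve::ode(y = c(a = 1, q = 1), times = seq(0, 50, 10),
                      func = function(tau, u, parms) {
                        list(unname(pgf_vector_field(u[1], u[2], p)))
                      }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[, "a"]), rep(1, 6), tolerance = 1e-9)
  expect_equal(unname(sol[, "q"]), rep(1, 6), tolerance = 1e-9)
})

test_that("TCP curves are monotone in time and in the death rates", {
  set.seed(32)
  t <- seq(0, 20, 0.5)
  for (i in 1:10) {
    p <- random_params()
    cv <- tcp_curve_characteristics(p, 6, 5, t)
    expect_true(all(cv$tcp >= 0 & cv$tcp <= 1))
    expect_true(all(diff(cv$tcp) >= -1e-9))
  }
  # nondecreasing in each death rate at fixed t
  at12 <- function(Ga, Gq) {
    p <- two_compartment_params(0.4, 0.3, 0.5, Ga, Gq)
    tcp_curve_characteristics(p, 6, 5, c(0, 12))$tcp[2]
  }
  sweep_Ga <- vapply(seq(0.1, 2, 0.1), at12, numeric(1), Gq = 0.5)
  sweep_Gq <- vapply(seq(0.1, 2, 0.1), function(g) at12(0.5, g), numeric(1))
  expect_true(all(diff(sweep_Ga) >= -1e-9))
  expect_true(all(diff(sweep_Gq) >= -1e-9))
})

test_that("time to control reports the first crossing", {
  p <- clinical_params()
  grid <- seq(0, 30, 0.01)
  tc <- time_to_control(p, 100, 100, grid)
  cv <- tcp_curve_characteristics(p, 100, 100, grid)
  expect_true(cv$tcp[match(tc, grid)] >= 0.99)
  expect_true(all(cv$tcp[grid < tc] < 0.99))
  # unreachable level on a short grid
  expect_true(is.na(time_to_control(p, 100, 100, seq(0, 2, 0.1))))
})
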