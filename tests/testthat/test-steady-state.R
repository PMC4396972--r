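test_that("(1,1) is always a fixed point and reported roots are exact", {
  set.seed(21)
  for (i in 1:50) {
    p <- random_params()
    expect_equal(unname(pgf_vector_field(1, 1, p)), c(0, 0))
    fp <- fixed_points(p)
    expect_equal(unname(fp$trivial), c(1, 1))
    if (length(fp$residuals)) expect_true(all(fp$residuals < 1e-10))
  }
})

test_that("single-type limit recovers the birth-death fixed point", {
  # f = 1, gamma = 0: active compartment decouples; a* = Gamma_a / mu
  p <- two_compartment_params(0.5, 0, 1, Gamma_a = 0.2, Gamma_q = 0.3)
  fp <- fixed_points(p)
  a_stars <- vapply(fp$nontrivial, `[[`, numeric(1), "a")
  expect_true(any(abs(a_stars - 0.2 / 0.5) < 1e-12))
})

test_that("clinical rates leave no fixed point inside the unit square", {
  p <- two_compartment_params(0.065, 0.05, 0, Gamma_a = 1.5, Gamma_q = 0.4)
  fp <- fixed_points(p)
  inside <- Filter(function(r) all(r >= 0) && all(r < 1 - 1e-8),
                   fp$nontrivial)
  expect_length(inside, 0)
  # oracle: Newton searches from a grid of starts find no interior zero
  for (s1 in seq(0.05, 0.95, length.out = 10)) {
    for (s2 in seq(0.05, 0.95, length.out = 10)) {
      root <- newton_fixed_point(p, c(s1, s2))
      if (!is.null(root)) {
        expect_false(all(root >= 0) && all(root < 1 - 1e-6))
      }
    }
  }
})

test_that("interior fixed points found by the quadratic match a Newton search", {
  # a clearly supercritical draw: low death rates
  p <- two_compartment_params(0.8, 0.4, 0.5, Gamma_a = 0.1, Gamma_q = 0.05)
  fp <- fixed_points(p)
  inside <- Filter(function(r) all(r >= 0) && all(r < 1), fp$nontrivial)
  expect_gte(length(inside), 1)
  r <- inside[[1]]
  nr <- newton_fixed_point(p, pmax(r - 0.05, 0))
  expect_false(is.null(nr))
  expect_equal(unname(nr), unname(r), tolerance = 1e-6)
})

test_that("steady-state TCP covers the trivial and clinical cases", {
  expect_equal(tcp_infinity(clinical_params(), 0, 0), 1)
  for (f in c(0, 0.5, 1)) {
    expect_identical(tcp_infinity(clinical_params(f = f), 100, 100), 1)
  }
  # no death channel: extinction impossible
  p0 <- two_compartment_params(0.3, 0.2, 0.5, Gamma_a = 0, Gamma_q = 0)
  expect_equal(tcp_infinity(p0, 1, 0), 0)
})

test_that("regime classification matches fixed-point location", {
  expect_equal(classify_regime(
    two_compartment_params(0.3, 0.2, 0.5, Gamma_a = 0, Gamma_q = 0)),
    "supercritical")
  # axis-intercept criticality for f = 0, Gamma_q = 0
  expect_equal(classify_regime(
    two_compartment_params(0.2, 0.1, 0, Gamma_a = 0.19, Gamma_q = 0)),
    "supercritical")
  expect_equal(classify_regime(
    two_compartment_params(0.2, 0.1, 0, Gamma_a = 0.21, Gamma_q = 0)),
    "subcritical")
  expect_equal(classify_regime(clinical_params()), "subcritical")
  set.seed(22)
  for (i in 1:100) {
    p <- random_params(eig_min = 0.05)
    interior <- !is.null(tumorcontrol:::minimal_interior_root(fixed_points(p)))
    expect_equal(classify_regime(p) == "supercritical", interior)
  }
})

test_that("steady-state TCP is monotone in the rates", {
  # nondecreasing in each death rate, nonincreasing in mu
  tcp_of <- function(mu, Ga, Gq) {
    tcp_infinity(two_compartment_params(mu, 0.3, 0.4, Ga, Gq), 5, 5)
  }
  sweep_Ga <- vapply(seq(0, 1, 0.05), function(g) tcp_of(0.8, g, 0.1),
                     numeric(1))
  sweep_Gq <- vapply(seq(0, 1, 0.05), function(g) tcp_of(0.8, 0.1, g),
                     numeric(1))
  sweep_mu <- vapply(seq(0.05, 1.5, 0.05), function(m) tcp_of(m, 0.2, 0.2),
                     numeric(1))
  expect_true(all(diff(sweep_Ga) >= -1e-12))
  expect_true(all(diff(sweep_Gq) >= -1e-12))
  expect_true(all(diff(sweep_mu) <= 1e-12))
  expect_true(all(c(sweep_Ga, sweep_Gq, sweep_mu) >= 0 &
                  c(sweep_Ga, sweep_Gq, sweep_mu) <= 1))
})

test_that("death-rate phase boundary has the predicted axis intercepts", {
  mu <- 0.065; gamma <- 0.05
  b <- phase_boundary_death_rates(mu, gamma, 0, c(0, mu))
  expect_equal(nrow(b), 2)
  expect_equal(b$Gamma_q[b$Gamma_a == 0], gamma, tolerance = 1e-9)
  expect_equal(b$Gamma_q[b$Gamma_a == mu], 0, tolerance = 1e-9)
  # the Gamma_a-axis intercept is mu for every f
  for (f in c(0.3, 0.7)) {
    bf <- phase_boundary_death_rates(mu, gamma, f, mu)
    expect_equal(bf$Gamma_q, 0, tolerance = 1e-9)
  }
})

test_that("f = 1 boundary is a vertical line: criticality ignores Gamma_q", {
  # eigenvalue-scan oracle over a (Gamma_a, Gamma_q) grid
  mu <- 0.065
  for (Gq in c(0, 0.2, 1)) {
    for (Ga in c(0.03, 0.064, 0.066, 0.2)) {
      p <- two_compartment_params(mu, 0.05, 1, Ga, Gq)
      expect_equal(classify_regime(p),
                   if (Ga < mu) "supercritical" else "subcritical")
    }
  }
  # and no finite crossing is reported off the line
  b <- phase_boundary_death_rates(mu, 0.05, 1, c(0.03, 0.2), Gamma_q_max = 5)
  expect_equal(nrow(b), 0)
})

test_that("boundary curves are ordered in f (asymmetry shifts the boundary up)", {
  grid <- seq(0.03, 0.06, by = 0.005)
  b0 <- phase_boundary_death_rates(0.065, 0.05, 0, grid, Gamma_q_max = 5)
  b5 <- phase_boundary_death_rates(0.065, 0.05, 0.5, grid, Gamma_q_max = 5)
  b7 <- phase_boundary_death_rates(0.065, 0.05, 0.7, grid, Gamma_q_max = 5)
  common <- Reduce(intersect, list(b0$Gamma_a, b5$Gamma_a, b7$Gamma_a))
  expect_gt(length(common), 3)
  g <- function(b) b$Gamma_q[match(common, b$Gamma_a)]
  expect_true(all(g(b5) >= g(b0) - 1e-9))
  expect_true(all(g(b7) >= g(b5) - 1e-9))
})

test_that("rate-plane boundary matches the closed-form criticality relation", {
  # f = 1: critical mu equals Gamma_a independent of gamma
  for (gam in c(0.1, 1)) {
    p_lo <- two_compartment_params(1.49, gam, 1, 1.5, 0.4)
    p_hi <- two_compartment_params(1.51, gam, 1, 1.5, 0.4)
    expect_equal(classify_regime(p_lo), "subcritical")
    expect_equal(classify_regime(p_hi), "supercritical")
  }
  # mu = 0: no birth channel, subcritical at any gamma
  expect_equal(classify_regime(
    two_compartment_params(0, 2, 0, 1.5, 0.4)), "subcritical")
  b <- phase_boundary_rates(1.5, 0.4, 0, mu_grid = c(0.5, 1), gamma_max = 50)
  expect_equal(nrow(b), 0)
  # f = 0 with the reference death rates: critical gamma solves
  # gamma (mu - Gamma_a) = Gamma_q (mu + Gamma_a) (determinant condition)
  b2 <- phase_boundary_rates(1.5, 0.4, 0, mu_grid = c(2, 3, 4), gamma_max = 50)
  expect_equal(b2$gamma, 0.4 * (b2$mu + 1.5) / (b2$mu - 1.5), tolerance = 1e-8)
})
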