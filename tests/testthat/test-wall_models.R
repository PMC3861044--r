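test_that("linear elastic wall follows Laplace's law", {
  w <- wall_linear(0.0063)
  expect_equal(wall_strain(w, 127), 0.8001)
  expect_equal(wall_strain(w, 0), 0)
  p <- c(40, 80, 120)
  expect_equal(wall_strain(w, 2 * p), 2 * wall_strain(w, p))
})

test_that("nonlinear wall: half-saturation, unstressed limit, stiffening", {
  w <- wall_nonlinear(A0 = 1, Am = 32.6, alpha = 150, k = 10)
  # at p = alpha the sigmoid sits at half saturation for any k:
  # A = (A0+Am)/2, strain = sqrt(A/A0) - 1 (independent evaluation)
  expect_equal(wall_strain(w, 150), sqrt((1 + 32.6) / 2) - 1)
  expect_equal(wall_strain(w, 0), 0)
  # stiffening: numeric slope at 300 below slope at 150
  slope <- function(p) (wall_strain(w, p + 0.5) - wall_strain(w, p - 0.5))
  expect_lt(slope(300), slope(150))
  # monotone and bounded above by the area ceiling
  p <- seq(0, 600, by = 1)
  eps <- wall_strain(w, p)
  expect_true(all(diff(eps) >= 0))
  expect_true(all(eps < sqrt(32.6 / 1) - 1))
  # analytic pressure derivative matches finite differences
  pp <- c(80, 120, 150, 220)
  fd <- (wall_strain(w, pp + 1e-4) - wall_strain(w, pp - 1e-4)) / 2e-4
  expect_equal(wall_strain_dp(w, pp), fd, tolerance = 1e-6)
  expect_error(wall_nonlinear(A0 = 5, Am = 3), "Am > A0")
})

test_that("elastic walls are memoryless: evaluation order is irrelevant", {
  w <- wall_nonlinear()
  p <- c(150, 80, 210, 115, 80)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(wall_strain(w, p)[perm], wall_strain(w, p[perm]))
})

test_that("SLS wall: equilibrium, creep against an independent integrator", {
  w <- wall_sls(0.0063, 0.028, 0.01)
  tg <- seq(0, 1, by = 0.001)
  # constant pressure from relaxed start stays at the elastic value
  const <- stimulus_step(115, 115, 0.5, 1)
  eps <- sls_strain_trajectory(w, const, tg)
  expect_equal(eps, rep(0.0063 * 115, length(tg)), tolerance = 1e-12)

  # step input: instantaneous jump + exponential creep; cross-check against
  # an adaptive Runge-Kutta solve of the same ODE
  st <- stimulus_step(115, 143, 0.3, 50)
  eps2 <- sls_strain_trajectory(w, st, tg)
  f <- function(t, x) (-x + w$k_wall * (pressure(st, t) +
                                          w$tau_b * pressure_deriv(st, t))) / w$tau_a
  x0 <- w$k_wall * (pressure(st, 0) + w$tau_b * pressure_deriv(st, 0))
  oracle <- drop(ode_rk45(f, x0, tg, atol = 1e-10, rtol = 1e-10))
  expect_equal(eps2, oracle, tolerance = 1e-6)
  # creep: partial instantaneous response then relaxation to the static value
  expect_equal(eps2[length(eps2)], 0.0063 * 143, tolerance = 1e-6)

  # vanishing relaxation times: trajectory collapses onto the elastic map
  w0 <- wall_sls(0.0063, 1e-3, 9e-4)
  sin_st <- stimulus_sinusoid(127, 5, 6.44, 46.84)
  eps3 <- sls_strain_trajectory(w0, sin_st, tg)
  expect_equal(eps3, 0.0063 * pressure(sin_st, tg), tolerance = 1e-4)
})

test_that("SLS shows hysteresis on a pressure cycle; elastic walls do not", {
  tri <- stimulus_ramp(80, 200, 0, 2, symmetric_descend = TRUE)
  tg <- seq(0, 4, by = 0.002)
  p <- pressure(tri, tg)
  loop_area <- function(eps) {
    n <- length(p)
    sum(p * eps[c(2:n, 1)] - p[c(2:n, 1)] * eps) / 2
  }
  a_sls <- loop_area(sls_strain_trajectory(wall_sls(0.0063, 0.1, 0.02),
                                           tri, tg))
  a_lin <- loop_area(wall_strain(wall_linear(0.0063), p))
  a_nl <- loop_area(wall_strain(wall_nonlinear(), p))
  expect_gt(abs(a_sls), 1e-4)
  expect_lt(abs(a_lin), 1e-10)
  expect_lt(abs(a_nl), 1e-10)
})

test_that("QLV reductions recover all three wall models", {
  sin_st <- stimulus_sinusoid(127, 5, 6.44, 46.84)
  sq_st <- stimulus_square(140, 180, 4.6, 8.7)
  tg_sin <- seq(0, 5, by = 0.001)
  tg_sq <- seq(0, 20, by = 0.001)

  for (st in list(sin_st, sq_st)) {
    tg <- if (inherits(st, "sinusoid_stimulus")) tg_sin else tg_sq
    # elastic kernels: pointwise equal to the algebraic strain
    for (w in list(wall_linear(0.0063), wall_nonlinear())) {
      out <- qlv_strain_trajectory(qlv_from_wall(w), st, tg)
      expect_equal(out, wall_strain(w, pressure(st, tg)), tolerance = 1e-6)
    }
    # SLS kernel: matches the ODE trajectory started from the same
    # (relaxed-history) initial strain
    w <- wall_sls(0.0063, 0.028, 0.01)
    out <- qlv_strain_trajectory(qlv_from_wall(w), st, tg)
    direct <- sls_strain_trajectory(w, st, tg,
                                    eps0 = wall_strain(w, pressure(st, tg[1])))
    expect_equal(out, direct, tolerance = 1e-5)
  }
})

test_that("Prony and direct-quadrature QLV paths agree", {
  st <- stimulus_sinusoid(127, 5, 6.44, 46.84)
  tg <- seq(0, 2, by = 0.002)
  spec <- qlv_from_wall(wall_sls(0.0063, 0.028, 0.01))
  fast <- qlv_strain_trajectory(spec, st, tg)
  slow <- qlv_strain_trajectory(spec, st, tg, method = "direct")
  expect_equal(fast, slow, tolerance = 1e-5)
})

test_that("wall JSON-style constructor guards hold", {
  expect_error(wall_linear(-1))
  expect_error(wall_sls(0.0063, tau_a = 0, tau_b = 0.01))
})
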