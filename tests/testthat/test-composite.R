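test_that("assemble builds the canonical family and guards oddballs", {
  m <- assemble("linear", 2, "linear",
                params = list(k_wall = 0.0063, alpha = c(0.5, 0.4),
                              beta = c(0.5, 2), s1 = 480, s2 = 100))
  expect_equal(m$name, "le-v2-l")
  expect_equal(nrow(baroafferent:::br_system(m, stimulus_step())$A), 2)

  pm <- assemble("nonlinear", 2, "integrate_fire",
                 params = list(alpha_chain = c(0.188, 0.4),
                               beta_chain = c(0.304, 2)))
  expect_equal(pm$name, "ne-v2-if")
  expect_true(pm$canonical)

  expect_warning(assemble("sls", 1, "linear"), "outside the canonical")
  expect_error(assemble("linear", 4, "linear"), "n in")
})

test_that("relaxed initial conditions are true fixed points", {
  # constant stimulus: states and firing stay constant over 10 s
  const <- stimulus_step(121, 121, 1, 1)
  tg <- seq(0, 10, by = 0.05)
  for (m in all_canonical_models()) {
    sim <- simulate_br(m, const, tg)
    expect_lt(max(abs(sweep(sim$states, 2, sim$states[1, ]))), 1e-10)
    expect_equal(sim$f, rep(sim$f[1], length(tg)))
  }
  # zero pressure gives the zero state for linear-wall models
  expect_equal(steady_initial_conditions(nominal_linear_model(2), 0, 0),
               c(0, 0))
})

test_that("sinusoid ICs: SLS wall uses dp0, chains solve the linear system", {
  st <- stimulus_sinusoid(127, 5, 6.44, 46.84)
  p0 <- pressure(st, 0); dp0 <- pressure_deriv(st, 0)
  m <- br_model(wall_sls(0.0063, 0.028, 0.01), voigt_chain(2),
                neuron_linear(480, 100))
  x0 <- steady_initial_conditions(m, p0, dp0)
  expect_equal(x0[1], 0.0063 * (p0 + 0.01 * dp0))
  expect_equal(x0[-1], chain_steady_state(m$chain, x0[1]))
  # elastic walls ignore dp0
  lm <- nominal_linear_model(2)
  expect_equal(steady_initial_conditions(lm, p0, dp0),
               steady_initial_conditions(lm, p0, 0))
})

test_that("V1 linear model equals the closed-form single-mode solution", {
  m <- nominal_linear_model(1)
  # steep step: the input settles almost instantly, so the post-overshoot
  # decay is a clean single chain mode
  st <- stimulus_step(115, 143, 2, 50)
  tg <- seq(0, 15, by = 0.01)
  sim <- simulate_br(m, st, tg)
  # independent route: adaptive RK45 on the scalar chain ODE
  cm <- chain_matrices(m$chain)
  u <- function(t) wall_strain(m$wall, pressure(st, t))
  x0 <- chain_steady_state(m$chain, u(0))
  xt <- ode_rk45(function(t, x) drop(cm$A %*% x) + cm$b * u(t), x0, tg,
                 atol = 1e-11, rtol = 1e-11)
  f_oracle <- linear_firing(u(tg) - xt[, 1], m$neuron)
  expect_equal(sim$f, f_oracle, tolerance = 1e-6)
  # post-step decay carries a single exponential mode
  ad <- adaptation_exponential_count(sim, tol = 1e-3)
  expect_equal(ad$count, 1L)
})

test_that("linear-wall linear-neuron pipeline obeys superposition", {
  m <- br_model(wall_linear(0.0063), voigt_chain(2, c(0.188, 0.4), c(0.304, 2)),
                neuron_linear(480, 100))
  tg <- seq(0, 12, by = 0.02)
  base <- stimulus_step(115, 115, 2, 1)
  f0 <- simulate_br(m, base, tg)$f
  d1 <- simulate_br(m, stimulus_step(115, 125, 2, 1), tg)$f - f0
  d2 <- simulate_br(m, stimulus_step(115, 135, 2, 1), tg)$f - f0
  expect_equal(d2, 2 * d1, tolerance = 1e-8)
})

test_that("grid refinement changes the firing trace by < 1e-6 relative", {
  m <- preferred_model()
  st <- stimulus_sinusoid(127, 5, 6.44, 46.84)
  coarse <- simulate_br(m, st, seq(0, 5, by = 0.01))
  fine <- simulate_br(m, st, seq(0, 5, by = 0.005))
  keep <- seq(1, length(fine$t), by = 2)
  expect_lt(max(abs(fine$f[keep] - coarse$f)) / max(abs(coarse$f)), 1e-6)
})

test_that("adapted discharge is the same approaching a level from above or below", {
  m <- preferred_model()
  tg <- seq(0, 60, by = 0.02)
  up <- simulate_br(m, stimulus_step(115, 140, 2, 1), tg)
  dn <- simulate_br(m, stimulus_step(165, 140, 2, 1), tg)
  f_up <- tail(up$f, 1); f_dn <- tail(dn$f, 1)
  expect_gt(f_up, 0)
  expect_equal(f_up, f_dn, tolerance = 1e-4)
})

test_that("simulation results are consistent containers", {
  sim <- simulate_br(preferred_model(), stimulus_square(), seq(0, 20, 0.01))
  lens <- lengths(sim[c("t", "pressure", "eps_w", "eps_ne", "f")])
  expect_true(all(lens == lens[1]))
  expect_true(all(sim$f >= 0))   # IF neuron never fires negatively
  df <- as.data.frame(sim)
  expect_named(df, c("time_s", "pressure_mmHg", "wall_strain", "ne_strain",
                     "firing_hz"))
  expect_error(simulate_br(preferred_model(), stimulus_square(), c(1, 1, 2)),
               "increasing")
})

test_that("lti_solve agrees with the adaptive RK oracle on all six models", {
  st <- stimulus_sinusoid(127, 5, 6.44, 46.84)
  tg <- seq(0, 3, by = 0.01)
  for (m in all_canonical_models()) {
    sys <- baroafferent:::br_system(m, st)
    x0 <- steady_initial_conditions(m, pressure(st, 0), pressure_deriv(st, 0))
    a <- lti_solve(sys$A, sys$d, sys$g, x0, tg)
    b <- ode_rk45(function(t, x) drop(sys$A %*% x) + sys$d * sys$g(t), x0, tg)
    expect_lt(max(abs(a - b)), 1e-6)
  }
})
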