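make_step_truth <- function() {
  model <- br_model(wall_linear(0.0063),
                    voigt_chain(2, c(0.5, 0.4), c(0.5, 2)),
                    neuron_linear(480, 100))
  stimulus <- stimulus_step(115, 143, 2, 1)
  t <- seq(0, 15, by = 0.02)
  f <- simulate_br(model, stimulus, t)$f
  list(model = model, stimulus = stimulus, dataset = br_dataset(t, f))
}

test_that("residuals follow the normalized pointwise definition", {
  w <- make_step_truth()
  r <- residuals_br(w$model, w$stimulus, w$dataset)
  expect_equal(r, rep(0, length(r)))
  # constant offset d on every observation -> every residual -d/fbar
  ds_off <- br_dataset(w$dataset$t, w$dataset$f_obs + 3)
  r_off <- residuals_br(w$model, w$stimulus, ds_off)
  expect_equal(r_off, rep(-3 / ds_off$f_mean, length(r_off)))
})

test_that("cost, RMSE and R^2 match hand arithmetic", {
  # toy: fbar = 100, pointwise errors (1, -2, 1) Hz
  r <- c(1, -2, 1) / 100
  expect_equal(r, c(0.01, -0.02, 0.01))
  expect_equal(cost_rmse(r), 1e-4 + 4e-4 + 1e-4)
  f_obs <- c(99, 102, 99)
  f_model <- f_obs + c(1, -2, 1)
  expect_equal(rmse_hz(f_model, f_obs), sqrt(mean(c(1, 4, 1))))
  expect_equal(r_squared(f_obs, f_obs), 1)
  expect_equal(r_squared(rep(mean(f_obs), 3), f_obs), 0)
})

test_that("sensitivities: affine structure and analytic oracle", {
  w <- make_step_truth()
  tg <- seq(0, 15, by = 0.1)
  sens <- sensitivities(w$model, w$stimulus, tg,
                        theta_names = c("s1", "s2", "alpha1"))
  # linear neuron: df/ds2 = 1 at all t, so the log-scaled column is s2
  expect_equal(sens$S[, "s2"], rep(100, length(tg)), tolerance = 1e-6)
  # df/ds1 = eps_ne(t): log-scaled column is s1 * eps_ne(t)
  sim <- simulate_br(w$model, w$stimulus, tg)
  expect_equal(sens$S[, "s1"], 480 * sim$eps_ne, tolerance = 1e-4)
  # a parameter the output does not depend on has zero sensitivity
  flat <- set_br_params(w$model, c(s1 = 1e-12))
  s0 <- sensitivities(flat, w$stimulus, tg, theta_names = "alpha1")
  expect_lt(max(abs(s0$S)), 1e-8)
})

test_that("subset selection prunes perfect correlation, keeps orthogonality", {
  t <- seq(0, 1, length.out = 50)
  c1 <- sin(2 * pi * t); c2 <- cos(2 * pi * t)
  # two parameters entering only as a sum: identical columns
  S_sum <- cbind(a = c1, b = c1, c = c2)
  sens <- structure(list(S = S_sum, t_grid = t,
                         ranking = sort(sqrt(colMeans(S_sum^2)),
                                        decreasing = TRUE)),
                    class = "br_sensitivity")
  sel <- rank_and_select(sens)
  expect_length(sel$selected, 2)
  expect_true("c" %in% sel$selected)
  expect_true(sum(c("a", "b") %in% sel$selected) == 1)
  # orthogonal columns: everything retained
  S_orth <- cbind(a = c1, b = c2, d = t - mean(t))
  sens2 <- structure(list(S = S_orth, t_grid = t,
                          ranking = sort(sqrt(colMeans(S_orth^2)),
                                         decreasing = TRUE)),
                     class = "br_sensitivity")
  expect_setequal(rank_and_select(sens2)$selected, c("a", "b", "d"))
  # ordering invariance
  perm <- c(3, 1, 2)
  sens3 <- sens2; sens3$S <- sens2$S[, perm]
  expect_setequal(rank_and_select(sens3)$selected,
                  rank_and_select(sens2)$selected)
})

test_that("V1 sinusoid configuration yields a four-parameter subset", {
  mod <- br_model(wall_linear(0.0063), voigt_chain(1, 0.5, 0.5),
                  neuron_linear(480, 100))
  st <- stimulus_sinusoid(127, 5, 6.45, 46.75)
  sens <- sensitivities(mod, st, seq(0, 5, by = 0.02),
                        theta_names = c("k_wall", "alpha1", "beta1", "s1",
                                        "s2", "stim.angular_frequency",
                                        "stim.phase"))
  sel <- rank_and_select(sens)
  expect_length(sel$selected, 4)
  # gain and compliance are exchangeable: only one of (k_wall, s1) survives
  expect_equal(sum(c("k_wall", "s1") %in% sel$selected), 1)
})

test_that("LM fitting: fixed point, recovery, and IF refusal", {
  w <- make_step_truth()
  sub <- c("s1", "s2", "alpha1", "beta1")
  # start at the truth: immediate convergence with ~zero cost
  ft0 <- fit_br(w$model, w$stimulus, w$dataset, sub)
  expect_true(ft0$converged)
  expect_lt(ft0$rmse, 1e-8)
  expect_gt(ft0$r2, 1 - 1e-12)
  # start perturbed 1.5x on every subset parameter: recover within 1e-3
  start <- set_br_params(w$model, br_params(w$model)[sub] * 1.5)
  ft <- fit_br(start, w$stimulus, w$dataset, sub)
  truth <- br_params(w$model)[sub]
  expect_lt(max(abs(ft$estimates - truth) / truth), 1e-3)
  expect_equal(ft$method, "lm")
  # LM must refuse integrate-and-fire models
  expect_error(fit_br(preferred_model(), w$stimulus, w$dataset, sub,
                      method = "lm"),
               "refused")
})

test_that("log-scale estimation keeps physical parameters positive", {
  w <- make_step_truth()
  ds_noisy <- br_dataset(w$dataset$t,
                         w$dataset$f_obs +
                           with_rng_seed(5, rnorm(length(w$dataset$t), 0, 2)))
  start <- set_br_params(w$model,
                         c(s1 = 200, s2 = 40, alpha1 = 1.2, beta1 = 0.2))
  ft <- fit_br(start, w$stimulus, ds_noisy, c("s1", "s2", "alpha1", "beta1"))
  expect_true(all(ft$estimates > 0))
})

test_that("simultaneous fit of replicated datasets matches the single fit", {
  w <- make_step_truth()
  sub <- c("s1", "s2")
  start <- set_br_params(w$model, c(s1 = 600, s2 = 80))
  single <- fit_br(start, w$stimulus, w$dataset, sub)
  joint <- fit_simultaneous(start, list(w$stimulus, w$stimulus),
                            list(w$dataset, w$dataset), sub)
  expect_equal(joint$estimates, single$estimates, tolerance = 1e-6)
  expect_error(fit_simultaneous(start, list(w$stimulus, w$stimulus),
                                list(w$dataset, w$dataset),
                                c("s1", "stim.t0")),
               "model parameters only")
})
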