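# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: matrix exponentials come from a scaling-and-
# squaring series (cross-checked against Matrix::expm when available), and
# the spike-train oracle integrates the membrane equation step by step with
# explicit reset.

# matrix exponential by scaling and squaring of the Taylor series
expm_series <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^s
  E <- diag(n)
  term <- diag(n)
  for (k in 1:30) {
    term <- term %*% As / k
    E <- E + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

# step response of dx/dt = A x + b*u (u constant) from x0, via expm
lti_step_response <- function(A, b, u, x0, t) {
  xinf <- solve(A, -b * u)
  t(vapply(t, function(tt) {
    drop(expm_series(A * tt) %*% (x0 - xinf)) + xinf
  }, numeric(length(x0))))
}

# event-based integrate-and-fire oracle: integrate Cm dV/dt = I - g V by
# RK4 stepping with bisection-refined threshold crossings and explicit
# reset + refractory hold; returns the mean inter-spike interval (s)
spike_isi_oracle <- function(I, neuron, dt = 1e-5, t_max = 2) {
  f <- function(v) 1000 * (I - neuron$g * v) / neuron$Cm  # mV/s
  rk4 <- function(v, h) {
    k1 <- f(v); k2 <- f(v + h / 2 * k1); k3 <- f(v + h / 2 * k2)
    k4 <- f(v + h * k3)
    v + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  v <- 0; t <- 0
  spikes <- numeric(0)
  nstep <- 0L
  while (t < t_max && length(spikes) < 25 && nstep < 5e6) {
    nstep <- nstep + 1L
    v_new <- rk4(v, dt)
    if (v_new >= neuron$Vth) {
      lo <- 0; hi <- dt
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        if (rk4(v, mid) >= neuron$Vth) hi <- mid else lo <- mid
      }
      t_cross <- t + (lo + hi) / 2
      spikes <- c(spikes, t_cross)
      t <- t_cross + neuron$Delta   # refractory hold, then restart from 0
      v <- 0
    } else {
      v <- v_new
      t <- t + dt
    }
  }
  if (length(spikes) < 3) return(Inf)
  mean(diff(spikes))
}

# evaluate expr under a fixed seed without disturbing the session RNG
with_rng_seed <- function(seed, expr)
  baroafferent:::with_preserved_rng(seed, expr)

# central finite difference of a scalar function
fd_central <- function(fun, x, h = 1e-6) (fun(x + h) - fun(x - h)) / (2 * h)

# bounded-effort simultaneous Nelder-Mead fit for replicate studies
fit_br_quiet <- function(start, stims, sets, subset) {
  fit_simultaneous(start, stims, sets, subset,
                   control = list(maxit = 500, reltol = 1e-8))
}

# canonical models at nominal parameters
nominal_linear_model <- function(n = 2) {
  br_model(wall_linear(0.0063),
           voigt_chain(n, c(0.5, 0.4, 1)[1:n], c(0.5, 2, 10)[1:n]),
           neuron_linear(480, 100))
}

all_canonical_models <- function() {
  list(
    "le-v1-l" = nominal_linear_model(1),
    "le-v2-l" = nominal_linear_model(2),
    "le-v3-l" = nominal_linear_model(3),
    "v-v2-l" = br_model(wall_sls(0.0063, 0.028, 0.01), voigt_chain(2),
                        neuron_linear(480, 100)),
    "ne-v2-l" = br_model(wall_nonlinear(1, 32.6, 150, 10), voigt_chain(2),
                         neuron_linear(619, 109)),
    "ne-v2-if" = preferred_model())
}
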