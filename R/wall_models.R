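#' Arterial wall models
#'
#' Three models map transmural pressure p (mmHg) to circumferential wall
#' strain \eqn{\epsilon_w} (unitless, zero at zero transmural pressure):
#'
#' * **linear elastic** (`wall_linear`): Laplace's law for a thin-walled
#'   isotropic tube gives \eqn{\epsilon_w = k_{wall}\, p} with
#'   \eqn{k_{wall} = r_0/(E h)} (1/mmHg) folding Young's modulus, wall
#'   thickness and unstressed radius into a single compliance.
#' * **nonlinear elastic** (`wall_nonlinear`): a sigmoidal pressure-area
#'   relationship
#'   \eqn{A(p) = A_0 + (A_m - A_0)\, p^k/(\alpha^k + p^k)}
#'   with strain defined through the radius ratio,
#'   \eqn{\epsilon_w = \sqrt{A(p)/A_0} - 1}; deformation saturates at both
#'   low and high pressure.
#' * **standard linear solid** (`wall_sls`): a Maxwell element in parallel
#'   with a spring; in pressure-strain form
#'   \deqn{\tau_a \dot\epsilon_w + \epsilon_w = k_{wall}(p + \tau_b \dot p),}
#'   i.e. elastic compliance `k_wall` at DC plus creep with relaxation time
#'   `tau_a` and an instantaneous response fraction `tau_b/tau_a`.
#'
#' All three are special cases of the quasi-linear viscoelastic (QLV)
#' convolution, see [qlv_spec()].
#'
#' @param k_wall compliance (1/mmHg), > 0
#' @return an object of class `c("<kind>_wall", "wall_model")`
#' @examples
#' w <- wall_linear(0.0063)
#' wall_strain(w, 127)   # 0.8001
#' @export
wall_linear <- function(k_wall = 0.0063) {
  stopifnot(k_wall > 0)
  structure(list(k_wall = k_wall),
            class = c("linear_wall", "wall_model"))
}

#' @rdname wall_linear
#' @param A0 unstressed cross-sectional area (mm^2), > 0
#' @param Am maximal area (mm^2), > `A0`
#' @param alpha characteristic saturation pressure (mmHg), > 0
#' @param k sigmoid steepness (unitless), > 0
#' @export
wall_nonlinear <- function(A0 = 1, Am = 32.6, alpha = 150, k = 10) {
  if (A0 >= Am) stop("wall_nonlinear requires Am > A0")
  stopifnot(A0 > 0, alpha > 0, k > 0)
  structure(list(A0 = A0, Am = Am, alpha = alpha, k = k),
            class = c("nonlinear_wall", "wall_model"))
}

#' @rdname wall_linear
#' @param tau_a creep (strain relaxation) time constant (s), > 0
#' @param tau_b stress relaxation time constant (s), > 0; `tau_b/tau_a` is
#'   the instantaneous fraction of the static elastic response
#' @export
wall_sls <- function(k_wall = 0.0063, tau_a = 0.028, tau_b = 0.01) {
  stopifnot(k_wall > 0, tau_a > 0, tau_b > 0)
  structure(list(k_wall = k_wall, tau_a = tau_a, tau_b = tau_b),
            class = c("sls_wall", "wall_model"))
}

#' Static elastic wall strain
#'
#' Evaluates the elastic (memoryless) pressure-to-strain map of a wall
#' model. For the SLS wall this is its static (fully relaxed) response
#' \eqn{k_{wall} p}; the dynamic trajectory is given by
#' [sls_strain_trajectory()]. `wall_strain_dp()` is the exact derivative
#' \eqn{d\epsilon_w/dp}, used to propagate analytic stimulus derivatives.
#'
#' @param wall a `wall_model`
#' @param p pressure vector (mmHg)
#' @return strain vector (unitless)
#' @export
wall_strain <- function(wall, p) UseMethod("wall_strain")

#' @rdname wall_strain
#' @export
wall_strain_dp <- function(wall, p) UseMethod("wall_strain_dp")

#' @export
wall_strain.linear_wall <- function(wall, p) wall$k_wall * p

#' @export
wall_strain_dp.linear_wall <- function(wall, p) rep(wall$k_wall, length(p))

#' @export
wall_strain.sls_wall <- function(wall, p) wall$k_wall * p

#' @export
wall_strain_dp.sls_wall <- function(wall, p) rep(wall$k_wall, length(p))

wall_area <- function(wall, p) {
  x <- (pmax(p, 0) / wall$alpha)^wall$k
  wall$A0 + (wall$Am - wall$A0) * x / (1 + x)
}

#' @export
wall_strain.nonlinear_wall <- function(wall, p) {
  sqrt(wall_area(wall, p) / wall$A0) - 1
}

#' @export
wall_strain_dp.nonlinear_wall <- function(wall, p) {
  x <- (pmax(p, 0) / wall$alpha)^wall$k
  dA <- (wall$Am - wall$A0) * wall$k * x /
    (pmax(p, .Machine$double.eps) * (1 + x)^2)
  dA / (2 * sqrt(wall_area(wall, p) * wall$A0))
}

#' @export
print.wall_model <- function(x, ...) {
  cat(sprintf("<wall model: %s>\n", sub("_wall$", "", class(x)[1])))
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Viscoelastic wall strain trajectory (standard linear solid)
#'
#' Integrates the SLS wall ODE
#' \eqn{\tau_a \dot\epsilon_w = -\epsilon_w + k_{wall}(p + \tau_b \dot p)}
#' along a pressure stimulus, starting from the relaxed state
#' \eqn{\epsilon_w(t_0) = k_{wall}(p(t_0) + \tau_b \dot p(t_0))}
#' (zero strain derivative at the initial instant). The scalar linear ODE is
#' solved exactly mode-by-mode with quadratically interpolated input
#' (see [lti_solve()]); `pressure_deriv()` supplies \eqn{\dot p}
#' analytically.
#'
#' @param wall an SLS wall from [wall_sls()]
#' @param stimulus a `pressure_stimulus`
#' @param t_grid increasing time grid (s)
#' @param eps0 optional initial strain; default is the relaxed value
#' @return strain vector on `t_grid`
#' @export
sls_strain_trajectory <- function(wall, stimulus, t_grid, eps0 = NULL) {
  check_grid(t_grid)
  u <- function(t) {
    wall$k_wall / wall$tau_a *
      (pressure(stimulus, t) + wall$tau_b * pressure_deriv(stimulus, t))
  }
  if (is.null(eps0)) eps0 <- wall$tau_a * u(t_grid[1])
  sol <- lti_solve(matrix(-1 / wall$tau_a, 1, 1), d = 1, g = u,
                   x0 = eps0, t_grid = t_grid)
  drop(sol)
}

check_grid <- function(t_grid) {
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least two points")
  invisible(t_grid)
}

#' Quasi-linear viscoelastic (QLV) wall specification
#'
#' In the QLV framework the wall strain is the convolution of a creep
#' kernel K with the rate of the elastic response:
#' \deqn{\epsilon_w(t) = \int_{-\infty}^{t} K(t-s)\,
#'   \frac{d\epsilon_e(p(s))}{ds}\, ds,}
#' with the pressure history before the record held at its initial value
#' (relaxed preload), so the history contributes
#' \eqn{K(\infty)\,\epsilon_e(p(t_0))}.
#'
#' Each wall model corresponds to a (creep, elastic response) pair:
#' linear elastic: \eqn{K \equiv 1}, \eqn{\epsilon_e = k_{wall} p};
#' nonlinear elastic: \eqn{K \equiv 1},
#' \eqn{\epsilon_e = \sqrt{A(p)/A_0} - 1}; SLS:
#' \eqn{K(t) = 1 - (1 - \tau_b/\tau_a) e^{-t/\tau_a}},
#' \eqn{\epsilon_e = k_{wall} p}. [qlv_from_wall()] builds the pair for any
#' wall model; this reduction is the module's central cross-check.
#'
#' Kernels of Prony (exponential-sum) form
#' \eqn{K(t) = k_\infty - \sum_i c_i e^{-t/\tau_i}} are integrated by exact
#' recursive filters (cost O(N)); arbitrary kernels fall back to direct
#' trapezoidal convolution (O(N^2), intended for oracle-scale grids).
#'
#' @param elastic function `p -> strain`, the elastic response
#' @param elastic_dp function `p -> d strain/dp` (exact derivative)
#' @param creep either a function `t -> K(t)` or a Prony list
#'   `list(k_inf=, c=, tau=)` with `K(t) = k_inf - sum(c_i exp(-t/tau_i))`
#' @return an object of class `qlv_spec`
#' @export
qlv_spec <- function(elastic, elastic_dp, creep) {
  if (!is.function(creep) &&
      !(is.list(creep) && all(c("k_inf", "c", "tau") %in% names(creep))))
    stop("creep must be a function or a Prony list(k_inf, c, tau)")
  structure(list(elastic = elastic, elastic_dp = elastic_dp, creep = creep),
            class = "qlv_spec")
}

#' @rdname qlv_spec
#' @param wall a `wall_model`
#' @export
qlv_from_wall <- function(wall) {
  el <- function(p) wall_strain(wall, p)
  el_dp <- function(p) wall_strain_dp(wall, p)
  creep <- if (inherits(wall, "sls_wall")) {
    list(k_inf = 1, c = 1 - wall$tau_b / wall$tau_a, tau = wall$tau_a)
  } else {
    list(k_inf = 1, c = numeric(0), tau = numeric(0))
  }
  qlv_spec(el, el_dp, creep)
}

#' QLV strain trajectory
#'
#' Evaluates the QLV convolution of a [qlv_spec()] along a pressure
#' stimulus on a uniform time grid, assuming relaxed preload at
#' `t_grid[1]`. The elastic-response rate is formed analytically as
#' \eqn{\epsilon_e'(p)\,\dot p}.
#'
#' @inheritParams sls_strain_trajectory
#' @param spec a `qlv_spec`
#' @param method `"auto"` uses exact recursive filtering for Prony kernels
#'   and direct quadrature otherwise; `"direct"` forces trapezoidal
#'   convolution (the independent oracle path)
#' @return strain vector on `t_grid`
#' @export
qlv_strain_trajectory <- function(spec, stimulus, t_grid,
                                  method = c("auto", "direct")) {
  check_grid(t_grid)
  method <- match.arg(method)
  p <- pressure(stimulus, t_grid)
  ratefun <- function(t)
    spec$elastic_dp(pressure(stimulus, t)) * pressure_deriv(stimulus, t)
  rate <- ratefun(t_grid)
  base <- spec$elastic(p[1])
  prony <- !is.function(spec$creep)
  if (method == "direct" || !prony) {
    Kfun <- if (prony) {
      function(t) spec$creep$k_inf -
        colSums(spec$creep$c * exp(-outer(1 / spec$creep$tau, t)))
    } else spec$creep
    n <- length(t_grid)
    out <- numeric(n)
    kinf <- if (prony) spec$creep$k_inf else {
      # assume the kernel settles within the record for the history term
      Kfun(t_grid[n] - t_grid[1])
    }
    for (i in seq_len(n)) {
      s <- t_grid[seq_len(i)]
      integrand <- Kfun(t_grid[i] - s) * rate[seq_len(i)]
      out[i] <- kinf * base + trapz(s, integrand)
    }
    return(out)
  }
  # Prony path: eps = k_inf*(base + cumulative integral of rate)
  #             - sum_i c_i * I_i,  I_i' = -I_i/tau_i + rate
  dt <- diff(t_grid)
  if (max(abs(dt - dt[1])) > 1e-10 * dt[1])
    stop("Prony QLV path requires a uniform grid; use method = 'direct'")
  mid <- ratefun(t_grid[-length(t_grid)] + dt / 2)
  # cumulative Simpson with analytic midpoint samples, O(dt^4)
  steps <- dt / 6 * (rate[-length(rate)] + 4 * mid + rate[-1])
  cumrate <- c(0, cumsum(steps))
  out <- spec$creep$k_inf * (base + cumrate)
  for (i in seq_along(spec$creep$c)) {
    Ii <- lti_solve(matrix(-1 / spec$creep$tau[i], 1, 1), d = 1,
                    g = ratefun, x0 = 0, t_grid = t_grid)
    out <- out - spec$creep$c[i] * drop(Ii)
  }
  out
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum((y[-1] + y[-length(y)]) / 2 * diff(x))
}
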