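#' Composite baroreceptor models
#'
#' A composite model couples one wall model, one Voigt chain and one neuron
#' into the algebraic-differential system
#' \deqn{\dot x = A x + b\,u(t), \qquad f = h(\epsilon_{ne}),}
#' where the differential states are the chain strains (plus the wall
#' strain for the viscoelastic wall) and pressure enters through the
#' algebraic wall map. The canonical family comprises six members, named
#' `<wall>-<chain>-<neuron>` with wall codes `le` (linear elastic), `v`
#' (viscoelastic SLS), `ne` (nonlinear elastic), chain codes `v1`..`v3`,
#' and neuron codes `l` (linear) or `if` (integrate-and-fire):
#' `le-v1-l`, `le-v2-l`, `le-v3-l`, `v-v2-l`, `ne-v2-l`, `ne-v2-if`.
#' Other combinations simulate fine but are flagged as outside the
#' canonical family.
#'
#' @param wall a `wall_model`
#' @param chain a [voigt_chain()]
#' @param neuron a `neuron_model`
#' @return an object of class `br_model`
#' @examples
#' m <- br_model(wall_linear(), voigt_chain(2), neuron_linear())
#' m$name  # "le-v2-l"
#' @export
br_model <- function(wall, chain, neuron) {
  stopifnot(inherits(wall, "wall_model"), inherits(chain, "voigt_chain"),
            inherits(neuron, "neuron_model"))
  wcode <- switch(class(wall)[1], linear_wall = "le", sls_wall = "v",
                  nonlinear_wall = "ne")
  ncode <- switch(class(neuron)[1], linear_neuron = "l", if_neuron = "if")
  name <- paste(wcode, paste0("v", chain$n), ncode, sep = "-")
  canonical <- name %in% c("le-v1-l", "le-v2-l", "le-v3-l", "v-v2-l",
                           "ne-v2-l", "ne-v2-if")
  if (!canonical)
    warning("model '", name, "' is outside the canonical six-model family",
            call. = FALSE)
  structure(list(wall = wall, chain = chain, neuron = neuron, name = name,
                 canonical = canonical),
            class = "br_model")
}

#' @rdname br_model
#' @param wall_kind `"linear"`, `"sls"` or `"nonlinear"`
#' @param n_voigt number of Voigt bodies (1-3)
#' @param neuron_kind `"linear"` or `"integrate_fire"`
#' @param params optional named list of component parameters overriding the
#'   nominal defaults (passed on to the component constructors)
#' @export
assemble <- function(wall_kind = c("linear", "sls", "nonlinear"),
                     n_voigt = 2,
                     neuron_kind = c("linear", "integrate_fire"),
                     params = list()) {
  wall_kind <- match.arg(wall_kind)
  neuron_kind <- match.arg(neuron_kind)
  pick <- function(fn, keys) do.call(fn, params[intersect(keys, names(params))])
  wall <- switch(wall_kind,
    linear = pick(wall_linear, "k_wall"),
    sls = pick(wall_sls, c("k_wall", "tau_a", "tau_b")),
    nonlinear = pick(wall_nonlinear, c("A0", "Am", "alpha", "k")))
  # 'alpha'/'beta' name the chain rates except under the nonlinear wall,
  # where 'alpha' is the wall's saturation pressure; use alpha_chain /
  # beta_chain to disambiguate (always honoured when present)
  chain_args <- list(n = n_voigt)
  if (wall_kind != "nonlinear") {
    if (!is.null(params$alpha)) chain_args$alpha <- params$alpha
    if (!is.null(params$beta)) chain_args$beta <- params$beta
  }
  if (!is.null(params$alpha_chain)) chain_args$alpha <- params$alpha_chain
  if (!is.null(params$beta_chain)) chain_args$beta <- params$beta_chain
  chain <- do.call(voigt_chain, chain_args)
  neuron <- switch(neuron_kind,
    linear = pick(neuron_linear, c("s1", "s2", "clamp")),
    integrate_fire = pick(neuron_if, c("Cm", "g", "Vth", "Delta", "s1", "s2")))
  br_model(wall, chain, neuron)
}

#' The preferred composite model
#'
#' Nonlinear elastic wall + two Voigt bodies + leaky integrate-and-fire
#' neuron (`ne-v2-if`): the member of the family that exhibits the full
#' battery of qualitative firing phenomena. Wall parameters are the
#' optimized sigmoid values (A0 = 1, Am = 32.6 mm^2, alpha = 150 mmHg,
#' k = 10); the chain uses estimated two-Voigt rates with partial
#' adaptation (DC gain ~0.35) and well-separated timescales
#' (alpha = (0.188, 0.4), beta = (0.304, 2) 1/s, relaxation times ~3.8 s
#' and ~0.49 s); the neuron uses the package's nodose-scale defaults. The
#' operating-point analysis behind these choices is laid out in the
#' methods vignette.
#'
#' @param neuron optionally substitute a different neuron (e.g. a linear
#'   amplifier for side-by-side comparisons)
#' @return a `br_model`
#' @export
preferred_model <- function(neuron = neuron_if()) {
  br_model(wall_nonlinear(A0 = 1, Am = 32.6, alpha = 150, k = 10),
           voigt_chain(2, alpha = c(0.188, 0.4), beta = c(0.304, 2)),
           neuron)
}

#' @export
print.br_model <- function(x, ...) {
  cat(sprintf("<composite BR model: %s%s>\n", x$name,
              if (x$canonical) "" else " (non-canonical)"))
  print(x$wall); print(x$chain); print(x$neuron)
  invisible(x)
}

n_states <- function(model) {
  model$chain$n + if (inherits(model$wall, "sls_wall")) 1L else 0L
}

# combined LTI system (A, d, g(t)) and output extractors for a model/stimulus
br_system <- function(model, stimulus) {
  cm <- chain_matrices(model$chain)
  if (inherits(model$wall, "sls_wall")) {
    w <- model$wall
    n <- model$chain$n
    A <- rbind(c(-1 / w$tau_a, rep(0, n)),
               cbind(cm$b, cm$A))
    d <- c(1, rep(0, n))
    g <- function(t) w$k_wall / w$tau_a *
      (pressure(stimulus, t) + w$tau_b * pressure_deriv(stimulus, t))
    list(A = A, d = d, g = g, wall_state = TRUE)
  } else {
    wall <- model$wall
    list(A = cm$A, d = cm$b,
         g = function(t) wall_strain(wall, pressure(stimulus, t)),
         wall_state = FALSE)
  }
}

#' Relaxed (steady) initial conditions
#'
#' Solves the zero-derivative system at the initial pressure `p0` and its
#' derivative `dp0`, so a simulation begins from a fully relaxed state.
#' For elastic walls the wall strain is algebraic,
#' \eqn{\epsilon_w(0) = \epsilon_e(p_0)}, and `dp0` does not enter; for the
#' SLS wall the relaxed wall state is
#' \eqn{\epsilon_w(0) = k_{wall}(p_0 + \tau_b\,\dot p_0)}. The chain state
#' solves \eqn{A x = -b\,\epsilon_w(0)}.
#'
#' @param model a `br_model`
#' @param p0 initial pressure (mmHg)
#' @param dp0 initial pressure derivative (mmHg/s)
#' @return state vector (wall state first when present, then cumulative
#'   chain strains)
#' @export
steady_initial_conditions <- function(model, p0, dp0 = 0) {
  eps_w0 <- if (inherits(model$wall, "sls_wall")) {
    model$wall$k_wall * (p0 + model$wall$tau_b * dp0)
  } else {
    wall_strain(model$wall, p0)
  }
  x_chain <- chain_steady_state(model$chain, eps_w0)
  if (inherits(model$wall, "sls_wall")) c(eps_w0, x_chain) else x_chain
}

#' Simulate a composite model
#'
#' Integrates the model's differential states along a pressure stimulus on
#' `t_grid` (exactly, via [lti_solve()]) and evaluates the algebraic
#' outputs: wall strain, nerve-ending strain and firing rate. By default
#' the simulation starts from the relaxed steady state at the initial
#' pressure (see [steady_initial_conditions()]).
#'
#' @param model a `br_model`
#' @param stimulus a `pressure_stimulus`
#' @param t_grid strictly increasing times (s); uniform grids use the fast
#'   recursive-filter path
#' @param x0 optional initial state (default: relaxed steady state)
#' @return a `br_simulation`: list with components `t`, `pressure`,
#'   `eps_w`, `eps_ne`, `f`, `states`, `model`, `stimulus`
#' @examples
#' sim <- simulate_br(preferred_model(), stimulus_square(),
#'                    seq(0, 20, by = 0.01))
#' range(sim$f)
#' @export
simulate_br <- function(model, stimulus, t_grid, x0 = NULL) {
  check_grid(t_grid)
  sys <- br_system(model, stimulus)
  if (is.null(x0)) {
    x0 <- steady_initial_conditions(model, pressure(stimulus, t_grid[1]),
                                    pressure_deriv(stimulus, t_grid[1]))
  }
  states <- lti_solve(sys$A, sys$d, sys$g, x0, t_grid)
  p <- pressure(stimulus, t_grid)
  if (sys$wall_state) {
    eps_w <- states[, 1]
    eps1 <- states[, 2]
  } else {
    eps_w <- wall_strain(model$wall, p)
    eps1 <- states[, 1]
  }
  eps_ne <- eps_w - eps1
  f <- firing_rate(model$neuron, eps_ne)
  structure(list(t = t_grid, pressure = p, eps_w = eps_w, eps_ne = eps_ne,
                 f = f, states = states, model = model, stimulus = stimulus),
            class = "br_simulation")
}

#' @export
as.data.frame.br_simulation <- function(x, ...) {
  data.frame(time_s = x$t, pressure_mmHg = x$pressure, wall_strain = x$eps_w,
             ne_strain = x$eps_ne, firing_hz = x$f)
}

#' @export
print.br_simulation <- function(x, ...) {
  cat(sprintf(
    "<BR simulation: %s, %d points, t in [%g, %g] s, f in [%.3g, %.3g] Hz>\n",
    x$model$name, length(x$t), min(x$t), max(x$t), min(x$f), max(x$f)))
  invisible(x)
}

#' @export
plot.br_simulation <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$pressure, type = "l", xlab = "time (s)",
                 ylab = "pressure (mmHg)", ...)
  graphics::plot(x$t, x$f, type = "l", xlab = "time (s)",
                 ylab = "firing rate (Hz)", ...)
  invisible(x)
}
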