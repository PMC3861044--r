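#' Pressure stimuli
#'
#' Constructors for the smooth pressure stimuli used to drive the afferent
#' baroreceptor models: a sinusoid (the classical 127 +/- 5 mmHg protocol),
#' a smooth tanh step, a smooth square pulse (two opposing tanh steps), and a
#' piecewise-linear ramp/triangle for qualitative experiments. All smooth
#' stimuli carry exact analytic time derivatives, which downstream components
#' (the viscoelastic wall, sensitivity analysis) consume; trajectories are
#' never differentiated numerically.
#'
#' The functional forms are
#' \deqn{p(t) = \bar p + a \sin(p_1 t + p_2)}{p(t) = pbar + a sin(p1 t + p2)}
#' for the sinusoid,
#' \deqn{p(t) = p_1 + \frac{p_2 - p_1}{2}\,(1 + \tanh(\theta (t - t_0)))}
#' for the step, and
#' \deqn{p(t) = p_b + \frac{\Delta p}{2}\,
#'   (\tanh(\gamma_1 (t - \delta_u)) - \tanh(\gamma_2 (t - \delta_d)))}
#' for the square pulse, so that a square pulse is exactly the superposition
#' of an up-step at \eqn{\delta_u} and a down-step at \eqn{\delta_d}.
#'
#' @param mean_pressure mean pressure \eqn{\bar p} (mmHg)
#' @param amplitude sinusoid amplitude (mmHg), must be >= 0
#' @param angular_frequency angular frequency \eqn{p_1} (rad/s), must be > 0
#' @param phase phase \eqn{p_2} (rad)
#' @return an object of class `c("<kind>_stimulus", "pressure_stimulus")`
#' @seealso [pressure()], [pressure_deriv()], [stimulus_from_json()]
#' @examples
#' s <- stimulus_sinusoid(127, 5, 6.44, 46.84)
#' pressure(s, c(0, 0.5, 1))
#' @export
stimulus_sinusoid <- function(mean_pressure = 127, amplitude = 5,
                              angular_frequency = 6.45, phase = 46.75) {
  stopifnot(amplitude >= 0, angular_frequency > 0)
  structure(
    list(mean_pressure = mean_pressure, amplitude = amplitude,
         angular_frequency = angular_frequency, phase = phase),
    class = c("sinusoid_stimulus", "pressure_stimulus"))
}

#' @rdname stimulus_sinusoid
#' @param p_base baseline pressure \eqn{p_1} (mmHg)
#' @param p_target post-step pressure \eqn{p_2} (mmHg)
#' @param t0 step onset (s); the trajectory passes through the midpoint
#'   \eqn{(p_1+p_2)/2} at `t0`
#' @param steepness step steepness \eqn{\theta} (1/s), must be > 0
#' @export
stimulus_step <- function(p_base = 115, p_target = 143, t0 = 2,
                          steepness = 1) {
  stopifnot(steepness > 0)
  structure(
    list(p_base = p_base, p_target = p_target, t0 = t0,
         steepness = steepness),
    class = c("step_stimulus", "pressure_stimulus"))
}

#' @rdname stimulus_sinusoid
#' @param p_up plateau pressure (mmHg)
#' @param t_up,t_down up- and down-transition times \eqn{\delta_u < \delta_d}
#'   (s)
#' @param gamma1,gamma2 rise and fall steepness (1/s); the default 50/s makes
#'   the transition width much smaller than the 4 s plateau of the classical
#'   square protocol
#' @export
stimulus_square <- function(p_base = 140, p_up = 180, t_up = 4.6,
                            t_down = 8.7, gamma1 = 50, gamma2 = 50) {
  stopifnot(t_up < t_down, gamma1 > 0, gamma2 > 0)
  structure(
    list(p_base = p_base, p_up = p_up, t_up = t_up, t_down = t_down,
         gamma1 = gamma1, gamma2 = gamma2),
    class = c("square_stimulus", "pressure_stimulus"))
}

#' @rdname stimulus_sinusoid
#' @param p_start,p_end ramp start and end pressures (mmHg)
#' @param t_start,t_end ramp start and end times (s), `t_start < t_end`
#' @param symmetric_descend if `TRUE` the ramp returns linearly to `p_start`
#'   over a second interval of the same length (a triangle wave cycle)
#' @export
stimulus_ramp <- function(p_start = 0, p_end = 250, t_start = 0, t_end = 25,
                          symmetric_descend = FALSE) {
  stopifnot(t_start < t_end)
  structure(
    list(p_start = p_start, p_end = p_end, t_start = t_start, t_end = t_end,
         symmetric_descend = symmetric_descend),
    class = c("ramp_stimulus", "pressure_stimulus"))
}

#' Evaluate a pressure stimulus
#'
#' `pressure()` evaluates a stimulus at times `t` (s) and returns pressure in
#' mmHg; `pressure_deriv()` returns the analytic time derivative dp/dt
#' (mmHg/s). For the ramp the derivative is the piecewise slope (taken
#' one-sided at the kinks).
#'
#' @param stim a `pressure_stimulus`
#' @param t numeric vector of times (s)
#' @return numeric vector, same length as `t`
#' @export
pressure <- function(stim, t) UseMethod("pressure")

#' @rdname pressure
#' @export
pressure_deriv <- function(stim, t) UseMethod("pressure_deriv")

#' @export
pressure.sinusoid_stimulus <- function(stim, t) {
  stim$mean_pressure +
    stim$amplitude * sin(stim$angular_frequency * t + stim$phase)
}

#' @export
pressure_deriv.sinusoid_stimulus <- function(stim, t) {
  stim$amplitude * stim$angular_frequency *
    cos(stim$angular_frequency * t + stim$phase)
}

#' @export
pressure.step_stimulus <- function(stim, t) {
  stim$p_base + (stim$p_target - stim$p_base) / 2 *
    (1 + tanh(stim$steepness * (t - stim$t0)))
}

#' @export
pressure_deriv.step_stimulus <- function(stim, t) {
  (stim$p_target - stim$p_base) / 2 * stim$steepness /
    cosh(stim$steepness * (t - stim$t0))^2
}

#' @export
pressure.square_stimulus <- function(stim, t) {
  dp <- stim$p_up - stim$p_base
  stim$p_base + dp / 2 * (tanh(stim$gamma1 * (t - stim$t_up)) -
                            tanh(stim$gamma2 * (t - stim$t_down)))
}

#' @export
pressure_deriv.square_stimulus <- function(stim, t) {
  dp <- stim$p_up - stim$p_base
  dp / 2 * (stim$gamma1 / cosh(stim$gamma1 * (t - stim$t_up))^2 -
              stim$gamma2 / cosh(stim$gamma2 * (t - stim$t_down))^2)
}

#' @export
pressure.ramp_stimulus <- function(stim, t) {
  dur <- stim$t_end - stim$t_start
  slope <- (stim$p_end - stim$p_start) / dur
  up <- stim$p_start + slope * pmin(pmax(t - stim$t_start, 0), dur)
  if (!stim$symmetric_descend) return(up)
  # triangle: descend over a mirrored second leg back to p_start
  tt <- t - stim$t_start
  p <- ifelse(tt <= dur, up,
              stim$p_end - slope * pmin(tt - dur, dur))
  ifelse(tt < 0, stim$p_start, p)
}

#' @export
pressure_deriv.ramp_stimulus <- function(stim, t) {
  dur <- stim$t_end - stim$t_start
  slope <- (stim$p_end - stim$p_start) / dur
  tt <- t - stim$t_start
  d <- ifelse(tt < 0 | tt > (if (stim$symmetric_descend) 2 * dur else dur),
              0, slope)
  if (stim$symmetric_descend) d <- ifelse(tt > dur, -slope, d)
  d
}

#' @export
print.pressure_stimulus <- function(x, ...) {
  kind <- sub("_stimulus$", "", class(x)[1])
  cat(sprintf("<pressure stimulus: %s>\n", kind))
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Stimulus JSON configuration
#'
#' Stimuli serialize to/from JSON blocks of the form
#' `{"type": "sinusoid"|"step"|"square"|"ramp", "params": {...}}`.
#'
#' @param stim a `pressure_stimulus`
#' @param path optional file path; if `NULL` the JSON string is returned
#' @return `stimulus_to_json()` a JSON string (invisibly, if written to file);
#'   `stimulus_from_json()` a `pressure_stimulus`
#' @export
stimulus_to_json <- function(stim, path = NULL) {
  type <- sub("_stimulus$", "", class(stim)[1])
  js <- jsonlite::toJSON(list(type = type, params = unclass(stim)),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname stimulus_to_json
#' @param x a JSON string, file path, or already-parsed list
#' @export
stimulus_from_json <- function(x) {
  cfg <- if (is.list(x)) x else jsonlite::fromJSON(x)
  if (is.null(cfg$type) || is.null(cfg$params))
    stop("stimulus config must have 'type' and 'params' fields")
  ctor <- switch(cfg$type,
                 sinusoid = stimulus_sinusoid,
                 step = stimulus_step,
                 square = stimulus_square,
                 ramp = stimulus_ramp,
                 stop("unknown stimulus type: ", cfg$type))
  do.call(ctor, as.list(cfg$params))
}
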