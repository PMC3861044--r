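#' Firing-rate neuron models
#'
#' Two algebraic maps from nerve-ending strain \eqn{\epsilon_{ne}} to
#' firing rate f (Hz):
#'
#' * **linear amplifier** (`neuron_linear`):
#'   \eqn{f = s_1 \epsilon_{ne} + s_2} with gain `s1` (Hz per unit strain)
#'   and shift `s2` (Hz). By default the output is *not* clamped at zero:
#'   the unclamped model's negative excursions under rectifying stimuli are
#'   a diagnostic feature, documenting why a threshold neuron is needed.
#' * **leaky integrate-and-fire** (`neuron_if`): an RC membrane (capacitance
#'   `Cm` nF, leak conductance `g` uS, voltage relative to the equilibrium
#'   potential) charged by a stimulus current affine in strain,
#'   \eqn{I = s_1 \epsilon_{ne} + s_2} (nA). The threshold-charging time
#'   for constant supra-threshold current is
#'   \deqn{T_{th} = \frac{C_m}{g}\,\ln\frac{I}{I - g V_{th}},}
#'   (the membrane time constant `Cm/g` is in ms for the nF/uS unit pair
#'   and is converted to seconds internally),
#'   and with absolute refractory period \eqn{\Delta} (s) the instantaneous
#'   rate is \eqn{f = 1/(T_{th} + \Delta)} for \eqn{I > g V_{th}}, else 0.
#'   f is continuous, monotone in strain, and bounded by \eqn{1/\Delta}
#'   (the default 7 ms refractory period reflects maximal observed rates of
#'   about 140 Hz).
#'
#' The membrane constants `Cm`, `g`, `Vth` and the current gain/shift are
#' package defaults chosen at nodose-neuron scales; see the methods
#' vignette for the reasoning.
#'
#' @param s1 gain (Hz per unit strain for the linear neuron; nA per unit
#'   strain for the IF stimulus current)
#' @param s2 shift (Hz, or nA)
#' @param clamp if `TRUE` the linear neuron output is truncated at 0 Hz
#' @return an object of class `c("<kind>_neuron", "neuron_model")`
#' @examples
#' linear_firing(0.05, neuron_linear(480, 100))   # 124
#' if_firing(2, neuron_if())
#' @export
neuron_linear <- function(s1 = 480, s2 = 100, clamp = FALSE) {
  structure(list(s1 = s1, s2 = s2, clamp = isTRUE(clamp)),
            class = c("linear_neuron", "neuron_model"))
}

#' @rdname neuron_linear
#' @param Cm membrane capacitance (nF), > 0
#' @param g leak conductance (uS), > 0
#' @param Vth threshold voltage relative to equilibrium (mV), > 0
#' @param Delta absolute refractory period (s), > 0
#' @export
neuron_if <- function(Cm = 10, g = 1, Vth = 10, Delta = 0.007,
                      s1 = 25, s2 = 7) {
  stopifnot(Cm > 0, g > 0, Vth > 0, Delta > 0)
  structure(list(Cm = Cm, g = g, Vth = Vth, Delta = Delta,
                 s1 = s1, s2 = s2),
            class = c("if_neuron", "neuron_model"))
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("<neuron model: %s>\n", sub("_neuron$", "", class(x)[1])))
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Linear amplifier firing rate
#'
#' \eqn{f = s_1 \epsilon_{ne} + s_2}; negative values are preserved unless
#' the neuron was built with `clamp = TRUE`.
#'
#' @param eps_ne nerve-ending strain (vector)
#' @param params a [neuron_linear()]
#' @return firing rate (Hz)
#' @export
linear_firing <- function(eps_ne, params) {
  f <- params$s1 * eps_ne + params$s2
  if (params$clamp) pmax(f, 0) else f
}

#' Integrate-and-fire stimulus current
#'
#' \eqn{I = s_1 \epsilon_{ne} + s_2} (nA): the mechanoreceptor channels are
#' modelled as injecting a current proportional to the sensed strain.
#'
#' @param eps_ne nerve-ending strain (vector)
#' @param params a [neuron_if()]
#' @return stimulus current (nA)
#' @export
stimulus_current <- function(eps_ne, params) {
  params$s1 * eps_ne + params$s2
}

#' Threshold-charging time
#'
#' Time for the membrane voltage to charge from equilibrium to `Vth` under
#' constant current `I` (the solution of the RC charging equation). For
#' \eqn{I \le g V_{th}} the leak wins and the voltage never reaches
#' threshold: the returned time is `Inf` (a valid sub-threshold outcome,
#' not an error).
#'
#' @param I stimulus current (nA, vector)
#' @param params a [neuron_if()]
#' @return charging time (s); `Inf` where sub-threshold
#' @export
threshold_time <- function(I, params) {
  leak <- params$g * params$Vth
  tau_m <- params$Cm / params$g * 1e-3   # nF / uS = ms -> s
  out <- rep(Inf, length(I))
  supra <- I > leak
  out[supra] <- tau_m * log(I[supra] / (I[supra] - leak))
  out
}

#' Integrate-and-fire firing rate
#'
#' \eqn{f = 1/(T_{th} + \Delta)} where supra-threshold, 0 where the
#' stimulus current is below the leak current at threshold voltage. Always
#' strictly less than \eqn{1/\Delta}.
#'
#' @inheritParams stimulus_current
#' @return firing rate (Hz)
#' @export
if_firing <- function(eps_ne, params) {
  I <- stimulus_current(eps_ne, params)
  Tth <- threshold_time(I, params)
  ifelse(is.finite(Tth), 1 / (Tth + params$Delta), 0)
}

#' Generic firing-rate map
#'
#' Dispatches to [linear_firing()] or [if_firing()] according to the
#' neuron kind.
#'
#' @param neuron a `neuron_model`
#' @param eps_ne nerve-ending strain (vector)
#' @return firing rate (Hz)
#' @export
firing_rate <- function(neuron, eps_ne) UseMethod("firing_rate")

#' @export
firing_rate.linear_neuron <- function(neuron, eps_ne)
  linear_firing(eps_ne, neuron)

#' @export
firing_rate.if_neuron <- function(neuron, eps_ne)
  if_firing(eps_ne, neuron)
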