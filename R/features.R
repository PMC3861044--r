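#' Qualitative firing-rate feature detectors
#'
#' Quantitative detectors for the six classical qualitative phenomena of
#' baroreceptor firing: threshold and saturation (ramp stimuli),
#' overshoot/adaptation timescale count (step), post-excitatory depression
#' (square pulse), asymmetry/hysteresis (triangle wave), and rectification
#' (large-amplitude sinusoid). Every detector is a deterministic function
#' of an existing [simulate_br()] result; detectors never re-simulate.
#'
#' Numerical conventions: a rate below `zero_tol` (default 1e-9 Hz) counts
#' as silent — exact zeros come from the sub-threshold branch of the
#' integrate-and-fire map, the tolerance only guards float noise.
#' "Sustained" firing for the threshold detector means positive firing for
#' the remainder of the (monotone) ramp.
#'
#' @name br_features
NULL

zero_tol_default <- 1e-9

#' Detect the firing threshold pressure on a ramp
#'
#' Lowest pressure at which the firing rate transitions from silence to
#' sustained positive firing under a monotone pressure ramp. Returns `NA`
#' if the trace never fires or fires throughout (no threshold within the
#' ramp).
#'
#' @param sim a `br_simulation` driven by a (non-triangle) ramp
#' @param zero_tol silence tolerance (Hz)
#' @return threshold pressure (mmHg) or `NA`
#' @export
detect_threshold <- function(sim, zero_tol = zero_tol_default) {
  firing <- sim$f > zero_tol
  if (all(firing) || !any(firing)) return(NA_real_)
  last_silent <- max(which(!firing))
  if (last_silent == length(firing)) return(NA_real_)  # never sustained
  sim$pressure[last_silent + 1L]
}

#' Detect the saturation firing level on a ramp
#'
#' Estimates a firing-rate plateau: the terminal value of f when the
#' terminal slope df/dp has fallen below `slope_frac` (default 5%) of the
#' maximal slope along the ramp. Returns `NA` when no plateau exists
#' (e.g. linear neuron on a linear wall).
#'
#' @param sim a `br_simulation` driven by a rising ramp
#' @param slope_frac terminal-slope criterion as a fraction of peak slope
#' @return saturation rate (Hz) or `NA`
#' @export
detect_saturation <- function(sim, slope_frac = 0.05) {
  dp <- diff(sim$pressure)
  keep <- dp > 0
  if (!any(keep)) return(NA_real_)
  dfdp <- diff(sim$f)[keep] / dp[keep]
  if (!length(dfdp)) return(NA_real_)
  peak <- max(abs(dfdp))
  if (peak == 0) return(NA_real_)
  m <- length(dfdp)
  tail_n <- max(5L, ceiling(0.02 * m))
  terminal <- mean(abs(dfdp[(m - tail_n + 1):m]))
  if (terminal < slope_frac * peak) sim$f[max(which(keep)) + 1L]
  else NA_real_
}

#' Post-excitatory depression silence duration
#'
#' Length (s) of the maximal contiguous silent interval after the
#' down-step of a square pressure pulse. Zero for models that cannot
#' cease firing (linear neuron).
#'
#' @param sim a `br_simulation` driven by a [stimulus_square()]
#' @param zero_tol silence tolerance (Hz)
#' @return silence duration (s), >= 0
#' @export
ped_silence_duration <- function(sim, zero_tol = zero_tol_default) {
  if (!inherits(sim$stimulus, "square_stimulus"))
    stop("ped_silence_duration expects a square-pulse simulation")
  after <- sim$t >= sim$stimulus$t_down
  # silence means pinned at zero (the sub-threshold branch); a linear
  # neuron's negative excursions are unphysical firing, not cessation
  silent <- abs(sim$f[after]) <= zero_tol
  if (!any(silent)) return(0)
  runs <- rle(silent)
  dt <- stats::median(diff(sim$t))
  max(runs$lengths[runs$values]) * dt
}

#' Hysteresis loop area
#'
#' Signed shoelace area of the (pressure, firing-rate) loop over one
#' complete symmetric up-down cycle (triangle stimulus). Memoryless static
#' models give zero area (up and down branches coincide); viscoelastic
#' coupling opens the loop.
#'
#' @param sim a `br_simulation` driven by a triangle
#'   (`stimulus_ramp(symmetric_descend = TRUE)`) covering one full cycle
#' @return signed loop area (mmHg * Hz)
#' @export
hysteresis_area <- function(sim) {
  st <- sim$stimulus
  if (!inherits(st, "ramp_stimulus") || !isTRUE(st$symmetric_descend))
    stop("hysteresis_area expects a symmetric triangle-ramp simulation")
  t_total <- st$t_start + 2 * (st$t_end - st$t_start)
  if (max(sim$t) < t_total - 1e-9)
    stop("incomplete cycle: simulation ends before the triangle returns")
  inside <- sim$t >= st$t_start & sim$t <= t_total
  p <- sim$pressure[inside]; f <- sim$f[inside]
  # closed-polygon shoelace area
  n <- length(p)
  sum(p * f[c(2:n, 1)] - p[c(2:n, 1)] * f) / 2
}

#' Count adaptation exponentials in a step response
#'
#' Fits sums of k = 1, 2, 3 decaying exponentials (plus an offset) to the
#' post-overshoot decay segment of a step response and returns the
#' smallest k whose RMS residual is below `tol` times the RMS of the
#' (centred) decay signal; additionally reports the residuals so nested
#' fits can be compared. Separable least squares: decay rates are
#' optimized by Nelder-Mead over log-rates with amplitudes solved
#' linearly. The default `tol` (0.5% of signal RMS) reflects that the
#' integrate-and-fire output is not an exact exponential sum even when the
#' underlying strain is; there is no literature criterion for this
#' detector, so the tolerance is a package definition.
#'
#' @param sim a `br_simulation` driven by a [stimulus_step()]
#' @param tol relative residual tolerance declaring a fit adequate
#' @return list with `count`, `residuals` (named numeric, RMS residual of
#'   the k-exponential fits), `segment` (the fitted time window)
#' @export
adaptation_exponential_count <- function(sim, tol = 5e-3) {
  if (!inherits(sim$stimulus, "step_stimulus"))
    stop("adaptation_exponential_count expects a step simulation")
  after <- which(sim$t > sim$stimulus$t0)
  ipk <- after[which.max(sim$f[after])]
  seg <- seq(ipk, length(sim$t))
  if (length(seg) < 10) stop("post-overshoot segment too short")
  tt <- sim$t[seg] - sim$t[seg[1]]
  y <- sim$f[seg]
  if (max(y) - min(y) < 1e-12) stop("non-decaying segment")
  scale_y <- sqrt(mean((y - mean(y))^2))
  fit_k <- function(k) {
    obj <- function(lr) {
      X <- cbind(1, exp(-tt %o% exp(lr)))
      co <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
      if (is.null(co) || any(!is.finite(co))) return(1e6)
      sqrt(mean((y - X %*% co)^2))
    }
    lr0 <- log(seq(0.3, 3, length.out = k))
    if (k == 1) {
      o <- stats::optimize(function(l) obj(l), interval = c(-6, 4))
      o$objective
    } else {
      o <- stats::optim(lr0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
      o2 <- stats::optim(o$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-12))
      o2$value
    }
  }
  res <- vapply(1:3, fit_k, numeric(1))
  names(res) <- paste0("k", 1:3)
  count <- which(res < tol * scale_y)
  count <- if (length(count)) min(count) else 3L
  list(count = as.integer(count), residuals = res,
       segment = range(sim$t[seg]))
}

#' Detect rectification under a periodic stimulus
#'
#' Rectification: under large-amplitude periodic forcing the firing rate
#' ceases during the trough of every cycle while remaining positive
#' elsewhere. The detector examines full cycles after a transient of
#' `skip_cycles` periods; it also reports the minimum firing value so that
#' the linear neuron's negative excursions (no true rectification, but
#' unphysiological negative rates) are visible.
#'
#' @param sim a `br_simulation` driven by a [stimulus_sinusoid()] covering
#'   at least `skip_cycles + 3` periods
#' @param skip_cycles transient cycles to discard
#' @param zero_tol silence tolerance (Hz)
#' @return list with `rectified` (flag), `min_f` (Hz), `silent_fraction`
#'   (fraction of each examined cycle spent silent, averaged)
#' @export
detect_rectification <- function(sim, skip_cycles = 2,
                                 zero_tol = zero_tol_default) {
  st <- sim$stimulus
  if (!inherits(st, "sinusoid_stimulus"))
    stop("detect_rectification expects a sinusoidal simulation")
  period <- 2 * pi / st$angular_frequency
  t0 <- sim$t[1] + skip_cycles * period
  n_cycles <- floor((max(sim$t) - t0) / period)
  if (n_cycles < 3)
    stop("need at least 3 post-transient cycles")
  per_cycle <- vapply(seq_len(n_cycles), function(k) {
    inside <- sim$t >= t0 + (k - 1) * period & sim$t < t0 + k * period
    fc <- sim$f[inside]
    # rectification clips the rate AT zero; negative excursions (linear
    # neuron) are recorded via min_f but do not count as cessation
    c(silent = mean(abs(fc) <= zero_tol), any_pos = any(fc > zero_tol))
  }, numeric(2))
  rectified <- all(per_cycle["silent", ] > 0) && all(per_cycle["any_pos", ] > 0)
  list(rectified = rectified, min_f = min(sim$f[sim$t >= t0]),
       silent_fraction = mean(per_cycle["silent", ]))
}

#' Full qualitative feature report
#'
#' Runs the detector battery on a named list of simulations (any subset of
#' `ramp`, `square`, `step`, `triangle`, `sinusoid`) and assembles a
#' feature report.
#'
#' @param sims named list of `br_simulation` objects
#' @return an object of class `br_feature_report`
#' @export
feature_report <- function(sims) {
  rep <- list()
  if (!is.null(sims$ramp)) {
    rep$threshold_pressure <- detect_threshold(sims$ramp)
    rep$saturation_rate <- detect_saturation(sims$ramp)
  }
  if (!is.null(sims$square))
    rep$ped_silence <- ped_silence_duration(sims$square)
  if (!is.null(sims$triangle))
    rep$hysteresis_area <- hysteresis_area(sims$triangle)
  if (!is.null(sims$step)) {
    ad <- adaptation_exponential_count(sims$step)
    rep$adaptation_exponentials <- ad$count
    rep$adaptation_residuals <- ad$residuals
  }
  if (!is.null(sims$sinusoid)) {
    rc <- detect_rectification(sims$sinusoid)
    rep$rectified <- rc$rectified
    rep$min_firing <- rc$min_f
  }
  structure(rep, class = "br_feature_report")
}

#' @export
print.br_feature_report <- function(x, ...) {
  cat("<BR qualitative feature report>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                paste(signif(unlist(v), 4), collapse = ", ")))
  }
  invisible(x)
}
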