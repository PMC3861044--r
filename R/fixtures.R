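#' Synthetic firing-rate datasets
#'
#' The original rat recordings behind the classical protocols (sinusoidal
#' forcing, four step increases, square pulse) are not distributable, so
#' the package generates synthetic stand-ins: a chosen composite model is
#' simulated under a protocol stimulus, sampled at a given rate, and
#' corrupted with Gaussian noise whose standard deviation is a fraction of
#' the trace's mean firing rate (matching the residual normalization used
#' in fitting). Generation is reproducible under a fixed seed and leaves
#' the caller's RNG state untouched.
#'
#' @param model generating `br_model`
#' @param stimulus a `pressure_stimulus`
#' @param duration record length (s)
#' @param sampling_rate samples per second (Hz), > 0
#' @param noise_sd_fraction noise SD as a fraction of the mean firing rate,
#'   >= 0
#' @param noise_type `"additive"` (SD = fraction x mean firing) or
#'   `"multiplicative"` (SD proportional to the local rate)
#' @param seed integer seed
#' @return an object of class `synthetic_spec`
#' @export
synthetic_spec <- function(model, stimulus, duration, sampling_rate = 50,
                           noise_sd_fraction = 0.02,
                           noise_type = c("additive", "multiplicative"),
                           seed = 1L) {
  stopifnot(sampling_rate > 0, noise_sd_fraction >= 0, duration > 0)
  structure(list(model = model, stimulus = stimulus, duration = duration,
                 sampling_rate = sampling_rate,
                 noise_sd_fraction = noise_sd_fraction,
                 noise_type = match.arg(noise_type),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @param spec a `synthetic_spec`
#' @return `generate_dataset()`: a [br_dataset()]
#' @export
generate_dataset <- function(spec) {
  t_grid <- seq(0, spec$duration, by = 1 / spec$sampling_rate)
  sim <- simulate_br(spec$model, spec$stimulus, t_grid)
  f <- sim$f
  if (spec$noise_sd_fraction > 0) {
    noise <- with_preserved_rng(spec$seed, stats::rnorm(length(f)))
    f <- switch(spec$noise_type,
      additive = f + spec$noise_sd_fraction * mean(f) * noise,
      multiplicative = f * (1 + spec$noise_sd_fraction * noise))
  }
  br_dataset(t_grid, f)
}

with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Bundled experimental protocols
#'
#' The six classical protocols as synthetic-data specifications: a
#' sinusoidal stimulus (mean 127 mmHg, amplitude 5 mmHg, 5 s record,
#' sampled at 200 Hz), four smooth step increases from a 115 mmHg baseline
#' to 128, 134, 137 and 143 mmHg (15 s records at 50 Hz), and a square
#' pulse 140 to 180 and back with a ~4 s plateau (20 s record at 50 Hz).
#'
#' @param model generating model for all protocols (default: the
#'   [preferred_model()])
#' @param noise_sd_fraction,seed passed to [synthetic_spec()]; each
#'   protocol gets a distinct sub-seed
#' @return named list of `synthetic_spec`s: `sinusoid`, `step1`..`step4`,
#'   `square`
#' @export
bundled_protocols <- function(model = preferred_model(),
                              noise_sd_fraction = 0.02, seed = 1L) {
  step_targets <- c(128, 134, 137, 143)
  specs <- list(
    sinusoid = synthetic_spec(model, stimulus_sinusoid(127, 5, 6.45, 46.75),
                              duration = 5, sampling_rate = 200,
                              noise_sd_fraction = noise_sd_fraction,
                              seed = seed))
  for (i in seq_along(step_targets)) {
    specs[[paste0("step", i)]] <- synthetic_spec(
      model, stimulus_step(115, step_targets[i], t0 = 2, steepness = 1),
      duration = 15, sampling_rate = 50,
      noise_sd_fraction = noise_sd_fraction, seed = seed + i)
  }
  specs$square <- synthetic_spec(
    model, stimulus_square(140, 180, t_up = 4.6, t_down = 8.7),
    duration = 20, sampling_rate = 50,
    noise_sd_fraction = noise_sd_fraction, seed = seed + 5L)
  specs
}

#' Read and write firing-rate time series
#'
#' Two-column CSV with header `time_s,firing_hz` for datasets;
#' [simulate_br()] results are written as five-column traces
#' (`time_s,pressure_mmHg,wall_strain,ne_strain,firing_hz`). Files are
#' UTF-8 with dot decimal separator; parsing is locale-independent.
#' Malformed numeric cells and non-monotone time stamps are reported with
#' their line numbers.
#'
#' @param path file path
#' @return `read_timeseries()`: a [br_dataset()]
#' @export
read_timeseries <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("time_s", "firing_hz") %in% names(raw)))
    stop("expected columns time_s, firing_hz in ", path)
  parse_col <- function(col, nm) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at line %d of %s",
                   nm, bad[1] + 1L, path))
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' at line %d of %s",
                   nm, which(is.na(v))[1] + 1L, path))
    v
  }
  t <- parse_col("time_s", "time_s")
  f <- parse_col("firing_hz", "firing_hz")
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono))
    stop(sprintf("non-monotone time at line %d of %s", nonmono[1] + 2L, path))
  br_dataset(t, f)
}

#' @rdname read_timeseries
#' @param x a [br_dataset()] or `br_simulation`
#' @export
write_timeseries <- function(x, path) {
  df <- if (inherits(x, "br_simulation")) {
    as.data.frame(x)
  } else if (inherits(x, "br_dataset")) {
    data.frame(time_s = x$t, firing_hz = x$f_obs)
  } else stop("write_timeseries handles br_dataset and br_simulation objects")
  df[] <- lapply(df, function(col) sprintf("%.17g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
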