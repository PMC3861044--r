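#' Flat parameter access for models and stimuli
#'
#' The estimation machinery works on a flat named numeric vector. For a
#' composite model the names are the component parameters (`k_wall`,
#' `tau_a`, `tau_b`; `A0`, `Am`, `alpha_w`, `k_w`; `alpha1..alpha3`,
#' `beta1..beta3`; `s1`, `s2`; `Cm`, `g`, `Vth`, `Delta`); for a stimulus
#' they are its own fields. `set_br_params()` / `set_stimulus_params()`
#' rebuild the object with a subset of entries replaced. In joint
#' model-plus-stimulus estimation, stimulus parameter names are prefixed
#' with `"stim."`.
#'
#' @param model a `br_model`
#' @return named numeric vector
#' @export
br_params <- function(model) {
  w <- model$wall
  wp <- switch(class(w)[1],
    linear_wall = c(k_wall = w$k_wall),
    sls_wall = c(k_wall = w$k_wall, tau_a = w$tau_a, tau_b = w$tau_b),
    nonlinear_wall = c(A0 = w$A0, Am = w$Am, alpha_w = w$alpha, k_w = w$k))
  ch <- model$chain
  cp <- stats::setNames(c(ch$alpha, ch$beta),
                        c(paste0("alpha", seq_len(ch$n)),
                          paste0("beta", seq_len(ch$n))))
  nn <- model$neuron
  np <- if (inherits(nn, "linear_neuron")) {
    c(s1 = nn$s1, s2 = nn$s2)
  } else {
    c(Cm = nn$Cm, g = nn$g, Vth = nn$Vth, Delta = nn$Delta,
      s1 = nn$s1, s2 = nn$s2)
  }
  c(wp, cp, np)
}

#' @rdname br_params
#' @param theta named numeric vector; a subset of `names(br_params(model))`
#' @export
set_br_params <- function(model, theta) {
  stopifnot(!is.null(names(theta)))
  full <- br_params(model)
  unknown <- setdiff(names(theta), names(full))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  full[names(theta)] <- theta
  w <- model$wall
  wall <- switch(class(w)[1],
    linear_wall = wall_linear(full[["k_wall"]]),
    sls_wall = wall_sls(full[["k_wall"]], full[["tau_a"]], full[["tau_b"]]),
    nonlinear_wall = wall_nonlinear(full[["A0"]], full[["Am"]],
                                    full[["alpha_w"]], full[["k_w"]]))
  n <- model$chain$n
  chain <- voigt_chain(n, full[paste0("alpha", seq_len(n))],
                       full[paste0("beta", seq_len(n))])
  neuron <- if (inherits(model$neuron, "linear_neuron")) {
    neuron_linear(full[["s1"]], full[["s2"]], model$neuron$clamp)
  } else {
    neuron_if(full[["Cm"]], full[["g"]], full[["Vth"]], full[["Delta"]],
              full[["s1"]], full[["s2"]])
  }
  br_model(wall, chain, neuron)
}

#' @rdname br_params
#' @param stim a `pressure_stimulus`
#' @export
stimulus_params <- function(stim) {
  v <- unlist(unclass(stim))
  v[vapply(unclass(stim), is.numeric, logical(1))]
}

#' @rdname br_params
#' @export
set_stimulus_params <- function(stim, theta) {
  stopifnot(!is.null(names(theta)))
  fields <- unclass(stim)
  unknown <- setdiff(names(theta), names(fields))
  if (length(unknown))
    stop("unknown stimulus parameter(s): ", paste(unknown, collapse = ", "))
  for (nm in names(theta)) fields[[nm]] <- unname(theta[[nm]])
  type <- sub("_stimulus$", "", class(stim)[1])
  stimulus_from_json(list(type = type, params = fields))
}

#' Model JSON configuration
#'
#' Composite models serialize to/from JSON blocks
#' `{"wall": {"type": ..., "params": {...}}, "chain": {"n": ...,
#' "alpha": [...], "beta": [...]}, "neuron": {"type": ..., "params":
#' {...}}}`.
#'
#' @param model a `br_model`
#' @param path optional file path
#' @return JSON string, or a `br_model` for `model_from_json()`
#' @export
model_to_json <- function(model, path = NULL) {
  wtype <- switch(class(model$wall)[1], linear_wall = "linear",
                  sls_wall = "sls", nonlinear_wall = "nonlinear")
  ntype <- switch(class(model$neuron)[1], linear_neuron = "linear",
                  if_neuron = "integrate_fire")
  cfg <- list(
    wall = list(type = wtype, params = unclass(model$wall)),
    chain = list(n = model$chain$n, alpha = model$chain$alpha,
                 beta = model$chain$beta),
    neuron = list(type = ntype, params = unclass(model$neuron)))
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname model_to_json
#' @param x a JSON string, file path, or parsed list
#' @export
model_from_json <- function(x) {
  cfg <- if (is.list(x)) x else jsonlite::fromJSON(x)
  for (f in c("wall", "chain", "neuron"))
    if (is.null(cfg[[f]])) stop("model config missing '", f, "' block")
  wall <- switch(cfg$wall$type,
    linear = do.call(wall_linear, as.list(cfg$wall$params)),
    sls = do.call(wall_sls, as.list(cfg$wall$params)),
    nonlinear = do.call(wall_nonlinear, as.list(cfg$wall$params)),
    stop("unknown wall type: ", cfg$wall$type))
  chain <- voigt_chain(cfg$chain$n, unlist(cfg$chain$alpha),
                       unlist(cfg$chain$beta))
  np <- as.list(cfg$neuron$params)
  neuron <- switch(cfg$neuron$type,
    linear = do.call(neuron_linear, np),
    integrate_fire = do.call(neuron_if, np),
    stop("unknown neuron type: ", cfg$neuron$type))
  br_model(wall, chain, neuron)
}
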