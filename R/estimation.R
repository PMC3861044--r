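#' Firing-rate dataset
#'
#' A recorded (or synthetic) firing-rate time series used for fitting:
#' times `t` (s), observed rates `f_obs` (Hz), and the set's average firing
#' rate `f_mean` (Hz), by which residuals are normalized.
#'
#' @param t increasing times (s)
#' @param f_obs observed firing rate (Hz)
#' @return an object of class `br_dataset`
#' @export
br_dataset <- function(t, f_obs) {
  stopifnot(length(t) == length(f_obs), length(t) >= 2, all(diff(t) > 0),
            all(is.finite(f_obs)))
  f_mean <- mean(f_obs)
  if (f_mean <= 0) stop("dataset mean firing rate must be positive")
  structure(list(t = t, f_obs = f_obs, f_mean = f_mean),
            class = "br_dataset")
}

#' @export
print.br_dataset <- function(x, ...) {
  cat(sprintf("<BR dataset: %d points, t in [%g, %g] s, mean f = %.3g Hz>\n",
              length(x$t), min(x$t), max(x$t), x$f_mean))
  invisible(x)
}

# apply a named theta (possibly with "stim." entries) to (model, stimulus)
apply_theta <- function(model, stimulus, theta) {
  if (is.null(theta) || !length(theta)) return(list(model = model,
                                                   stimulus = stimulus))
  stim_idx <- startsWith(names(theta), "stim.")
  if (any(!stim_idx))
    model <- set_br_params(model, theta[!stim_idx])
  if (any(stim_idx)) {
    th_s <- theta[stim_idx]
    names(th_s) <- sub("^stim\\.", "", names(th_s))
    stimulus <- set_stimulus_params(stimulus, th_s)
  }
  list(model = model, stimulus = stimulus)
}

predict_firing <- function(model, stimulus, t) {
  simulate_br(model, stimulus, t)$f
}

#' Normalized residuals
#'
#' Pointwise residuals between model and data, normalized by the set's
#' average firing rate:
#' \eqn{r_j = (f_{model}(t_j; \theta) - f_{obs,j}) / \bar f}.
#'
#' @param model a `br_model`
#' @param stimulus a `pressure_stimulus`
#' @param dataset a [br_dataset()]
#' @param theta optional named parameter overrides (model parameters, plus
#'   `stim.`-prefixed stimulus parameters)
#' @return numeric residual vector (unitless)
#' @export
residuals_br <- function(model, stimulus, dataset, theta = NULL) {
  ms <- apply_theta(model, stimulus, theta)
  fm <- predict_firing(ms$model, ms$stimulus, dataset$t)
  (fm - dataset$f_obs) / dataset$f_mean
}

#' Cost, RMSE and coefficient of determination
#'
#' `cost_rmse()` is the minimized least-squares cost, the sum of squared
#' normalized residuals \eqn{J = \sum_j r_j^2}. `rmse_hz()` is the reported
#' root-mean-square error in Hz, \eqn{\sqrt{\mathrm{mean}((f_m -
#' f_{obs})^2)}}; `r_squared()` is the usual coefficient of determination
#' of the model prediction against the observations.
#'
#' @param r normalized residual vector
#' @return scalar
#' @export
cost_rmse <- function(r) {
  stopifnot(length(r) > 0)
  sum(r^2)
}

#' @rdname cost_rmse
#' @param f_model,f_obs model and observed firing rates (Hz)
#' @export
rmse_hz <- function(f_model, f_obs) sqrt(mean((f_model - f_obs)^2))

#' @rdname cost_rmse
#' @export
r_squared <- function(f_model, f_obs) {
  1 - sum((f_obs - f_model)^2) / sum((f_obs - mean(f_obs))^2)
}

#' Finite-difference output sensitivities
#'
#' Time-resolved sensitivities of the firing rate with respect to
#' log-scaled parameters \eqn{\theta = \theta_0 e^x} (the scaling that
#' removes structural non-identifiability of the spring/dashpot constants
#' and enforces positivity), computed by central differences with relative
#' step `h`. The default `h = 1e-4` is the square root of the integration
#' tolerance (1e-8), balancing truncation against solver error.
#'
#' @param model a `br_model`
#' @param stimulus a `pressure_stimulus`
#' @param t_grid evaluation times (s)
#' @param theta_names parameters to differentiate (default: all model
#'   parameters); `stim.`-prefixed names address stimulus parameters
#' @param h relative finite-difference step
#' @return an object of class `br_sensitivity`: list with the sensitivity
#'   matrix `S` (time x parameter), `ranking` (time-averaged two-norms,
#'   descending), `t_grid`, `theta0`
#' @export
sensitivities <- function(model, stimulus, t_grid,
                          theta_names = names(br_params(model)),
                          h = 1e-4) {
  theta0 <- c(br_params(model),
              stats::setNames(stimulus_params(stimulus),
                              paste0("stim.", names(stimulus_params(stimulus)))))
  unknown <- setdiff(theta_names, names(theta0))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  if (any(theta0[theta_names] <= 0))
    stop("log-scaled sensitivities require strictly positive parameters")
  S <- matrix(0, length(t_grid), length(theta_names),
              dimnames = list(NULL, theta_names))
  for (j in seq_along(theta_names)) {
    nm <- theta_names[j]
    up <- stats::setNames(theta0[nm] * exp(h), nm)
    dn <- stats::setNames(theta0[nm] * exp(-h), nm)
    ms_up <- apply_theta(model, stimulus, up)
    ms_dn <- apply_theta(model, stimulus, dn)
    S[, j] <- (predict_firing(ms_up$model, ms_up$stimulus, t_grid) -
                 predict_firing(ms_dn$model, ms_dn$stimulus, t_grid)) / (2 * h)
  }
  norms <- sqrt(colMeans(S^2))
  structure(list(S = S, t_grid = t_grid,
                 ranking = sort(norms, decreasing = TRUE),
                 theta0 = theta0[theta_names]),
            class = "br_sensitivity")
}

#' @export
print.br_sensitivity <- function(x, ...) {
  cat("<BR sensitivity report>\nranking (time-averaged two-norm):\n")
  print(signif(x$ranking, 4))
  invisible(x)
}

#' Identifiable-subset selection
#'
#' Selects a practically identifiable parameter subset from a sensitivity
#' report in three stages: (1) parameters whose time-averaged two-norm
#' sensitivity falls below `sens_tol` times the largest are labelled
#' insensitive and fixed; (2) QR-with-column-pivoting on the leading right
#' singular vectors of the sensitivity matrix (numerical rank at relative
#' tolerance `svd_tol`) orders the sensitive parameters by linear
#' independence and keeps the first rank-many; (3) pairwise correlations
#' from the covariance \eqn{C = \sigma^2 (S^T S)^{-1}},
#' \eqn{c_{ij} = C_{ij}/\sqrt{C_{ii} C_{jj}}}, are pruned: while any
#' \eqn{|c_{ij}| > \gamma}, the less sensitive member of the worst pair is
#' fixed. Correlation coefficients do not depend on \eqn{\sigma^2}.
#' A rank-deficient sensitivity matrix yields a reduced subset, never an
#' error. The result is invariant to the ordering of the input parameters.
#'
#' @param sens a [sensitivities()] report
#' @param gamma correlation threshold (default 0.9)
#' @param svd_tol relative singular-value tolerance for numerical rank
#' @param sens_tol relative sensitivity threshold below which a parameter
#'   is fixed outright
#' @return an object of class `br_subset`: list with `selected`, `fixed`,
#'   `ranking`, `correlation` (matrix over the selected subset before
#'   pruning), `qr_order`
#' @export
rank_and_select <- function(sens, gamma = 0.9, svd_tol = 1e-8,
                            sens_tol = 1e-7) {
  norms <- sqrt(colMeans(sens$S^2))
  sensitive <- names(norms)[norms > sens_tol * max(norms)]
  fixed <- setdiff(colnames(sens$S), sensitive)
  S <- sens$S[, sensitive, drop = FALSE]
  sv <- svd(S)
  rho <- sum(sv$d > svd_tol * sv$d[1])
  qrp <- qr(t(sv$v[, seq_len(rho), drop = FALSE]), LAPACK = TRUE)
  qr_order <- sensitive[qrp$pivot]
  selected <- qr_order[seq_len(rho)]
  fixed <- union(fixed, setdiff(sensitive, selected))
  # correlation pruning on the selected subset
  corr_of <- function(cols) {
    Ss <- S[, cols, drop = FALSE]
    Ci <- tryCatch(solve(crossprod(Ss)), error = function(e) NULL)
    if (is.null(Ci)) return(NULL)
    stats::cov2cor(Ci)
  }
  corr0 <- corr_of(selected)
  repeat {
    if (length(selected) < 2) break
    cc <- corr_of(selected)
    if (is.null(cc)) {  # numerically singular: drop least sensitive
      drop_nm <- selected[which.min(norms[selected])]
      fixed <- c(fixed, drop_nm)
      selected <- setdiff(selected, drop_nm)
      next
    }
    off <- abs(cc); diag(off) <- 0
    if (max(off) <= gamma) break
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    pair <- selected[worst]
    drop_nm <- pair[which.min(norms[pair])]
    fixed <- c(fixed, drop_nm)
    selected <- setdiff(selected, drop_nm)
  }
  structure(list(selected = selected, fixed = sort(fixed),
                 ranking = sort(norms, decreasing = TRUE),
                 correlation = corr0, qr_order = qr_order),
            class = "br_subset")
}

#' @export
print.br_subset <- function(x, ...) {
  cat("<BR parameter subset>\n  selected:", paste(x$selected, collapse = ", "),
      "\n  fixed:   ", paste(x$fixed, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a composite model to a firing-rate dataset
#'
#' Minimizes the sum of squared normalized residuals over a parameter
#' subset, on the log scale \eqn{\theta = \theta_0 e^x} (estimates are
#' therefore always positive). Smooth models (linear neuron) use the
#' Levenberg-Marquardt method; models containing the integrate-and-fire
#' neuron have a piecewise-defined output, so the gradient-based LM method
#' is refused for them and the derivative-free Nelder-Mead method (with
#' one restart from the converged simplex) is used instead.
#'
#' @param model a `br_model` (its current parameters are the starting
#'   point and the nominal values of the log scaling)
#' @param stimulus a `pressure_stimulus`
#' @param dataset a [br_dataset()]
#' @param subset character vector of parameter names to estimate
#'   (`stim.`-prefixed names address stimulus parameters)
#' @param method `"lm"` or `"nm"`; default picks LM for smooth models,
#'   Nelder-Mead for integrate-and-fire models
#' @param control list of optimizer settings (`maxit`, `reltol`)
#' @return an object of class `br_fit`: estimates (physical scale), fitted
#'   model and stimulus, `rmse` (Hz), `r2`, `cost` trace, `iterations`,
#'   `method`, `converged`
#' @export
fit_br <- function(model, stimulus, dataset, subset,
                   method = NULL, control = list()) {
  fit_core(model, stimulus, list(dataset), list(stimulus), subset, method,
           control, single = TRUE)
}

#' @rdname fit_br
#' @param stimuli list of stimuli, one per dataset
#' @param datasets list of [br_dataset()]s; a single parameter vector is
#'   estimated against the pooled cost of all stimulus/dataset pairs
#' @export
fit_simultaneous <- function(model, stimuli, datasets, subset,
                             method = NULL, control = list()) {
  stopifnot(length(stimuli) == length(datasets), length(datasets) >= 2)
  if (any(startsWith(subset, "stim.")))
    stop("simultaneous fits estimate shared model parameters only")
  fit_core(model, stimuli[[1]], datasets, stimuli, subset, method, control,
           single = FALSE)
}

fit_core <- function(model, stimulus, datasets, stimuli, subset, method,
                     control, single) {
  stopifnot(length(subset) >= 1)
  is_if <- inherits(model$neuron, "if_neuron")
  if (is.null(method)) method <- if (is_if) "nm" else "lm"
  method <- match.arg(method, c("lm", "nm"))
  if (method == "lm" && is_if)
    stop("Levenberg-Marquardt refused: the integrate-and-fire output is ",
         "piecewise-defined (non-smooth at threshold); use method = 'nm'")
  theta_all <- c(br_params(model),
                 stats::setNames(stimulus_params(stimulus),
                                 paste0("stim.",
                                        names(stimulus_params(stimulus)))))
  unknown <- setdiff(subset, names(theta_all))
  if (length(unknown))
    stop("unknown parameter(s) in subset: ", paste(unknown, collapse = ", "))
  theta0 <- theta_all[subset]
  if (any(theta0 <= 0))
    stop("log-scale estimation requires positive starting values")

  resid_fun <- function(x) {
    theta <- stats::setNames(theta0 * exp(x), subset)
    unlist(lapply(seq_along(datasets), function(i) {
      tryCatch(
        residuals_br(model, stimuli[[i]], datasets[[i]], theta),
        error = function(e) rep(1e6, length(datasets[[i]]$t)))
    }))
  }
  x0 <- rep(0, length(subset))
  if (method == "lm") {
    opt <- levenberg_marquardt(resid_fun, x0,
                               maxit = control$maxit %||% 100,
                               reltol = control$reltol %||% 1e-10)
  } else {
    obj <- function(x) sum(resid_fun(x)^2)
    ctl <- list(maxit = control$maxit %||% 2000,
                reltol = control$reltol %||% 1e-10)
    o1 <- stats::optim(x0, obj, method = "Nelder-Mead", control = ctl)
    o2 <- stats::optim(o1$par, obj, method = "Nelder-Mead", control = ctl)
    opt <- list(par = o2$par, cost = c(o1$value, o2$value),
                iterations = o1$counts[1] + o2$counts[1],
                converged = o2$convergence == 0)
  }
  theta_hat <- stats::setNames(theta0 * exp(opt$par), subset)
  ms <- apply_theta(model, stimulus, theta_hat)
  per_set <- lapply(seq_along(datasets), function(i) {
    msi <- apply_theta(model, stimuli[[i]], theta_hat)
    fm <- predict_firing(msi$model, msi$stimulus, datasets[[i]]$t)
    list(rmse = rmse_hz(fm, datasets[[i]]$f_obs),
         r2 = r_squared(fm, datasets[[i]]$f_obs),
         residual_mean = mean((fm - datasets[[i]]$f_obs) /
                                datasets[[i]]$f_mean))
  })
  f_all <- unlist(lapply(seq_along(datasets), function(i) {
    msi <- apply_theta(model, stimuli[[i]], theta_hat)
    predict_firing(msi$model, msi$stimulus, datasets[[i]]$t)
  }))
  obs_all <- unlist(lapply(datasets, `[[`, "f_obs"))
  structure(list(
    estimates = theta_hat, subset = subset,
    model = ms$model, stimulus = if (single) ms$stimulus else NULL,
    rmse = rmse_hz(f_all, obs_all), r2 = r_squared(f_all, obs_all),
    per_dataset = per_set,
    cost = opt$cost, iterations = opt$iterations, method = method,
    converged = opt$converged),
    class = "br_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.br_fit <- function(x, ...) {
  cat(sprintf("<BR fit: %s, %s, %sconverged>\n", x$model$name, x$method,
              if (x$converged) "" else "NOT "))
  print(signif(x$estimates, 4))
  cat(sprintf("  RMSE = %.4g Hz, R^2 = %.4f, iterations = %d\n",
              x$rmse, x$r2, x$iterations))
  invisible(x)
}

# Levenberg-Marquardt for residual vectors with numeric forward-difference
# Jacobian; damping scaled by the diagonal of J^T J (Marquardt scaling).
levenberg_marquardt <- function(resid_fun, x0, maxit = 100, reltol = 1e-10,
                                fd_step = 1e-6) {
  x <- x0
  r <- resid_fun(x)
  cost <- sum(r^2)
  trace <- cost
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    J <- vapply(seq_along(x), function(j) {
      xp <- x; xp[j] <- xp[j] + fd_step
      (resid_fun(xp) - r) / fd_step
    }, numeric(length(r)))
    g <- crossprod(J, r)
    H <- crossprod(J)
    accepted <- FALSE
    for (k in 1:12) {
      step <- tryCatch(
        solve(H + lambda * diag(diag(H) + 1e-12, nrow(H)), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        xn <- x + drop(step)
        rn <- resid_fun(xn)
        cn <- sum(rn^2)
        if (is.finite(cn) && cn <= cost) {
          rel <- (cost - cn) / max(cost, 1e-300)
          x <- xn; r <- rn; cost <- cn
          lambda <- max(lambda / 3, 1e-12)
          accepted <- TRUE
          trace <- c(trace, cost)
          if (rel < reltol || max(abs(step)) < 1e-10) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 3
    }
    if (!accepted) { converged <- TRUE; break }
    if (converged) break
  }
  list(par = x, cost = trace, iterations = iter, converged = converged)
}
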