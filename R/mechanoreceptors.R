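#' Voigt-chain mechanoreceptor coupling
#'
#' The strain sensed by the mechanoreceptive nerve endings is coupled to the
#' arterial wall strain through n Voigt bodies (spring K_i parallel to
#' dashpot B_i) in series with a spring K (n = 1, 2, 3). The rate
#' parameters are \eqn{\alpha_i = K/B_i} and \eqn{\beta_i = (K+K_i)/B_i}
#' (1/s); the spring and dashpot constants themselves are not separately
#' identifiable. Physical (positive-stiffness) configurations have
#' \eqn{\beta_i > \alpha_i}; \eqn{\beta_i = \alpha_i} corresponds to a
#' degenerate Voigt body with zero spring (a pure dashpot), under which the
#' chain transmits no static strain (complete adaptation).
#'
#' The state variables are the cumulative Voigt strains
#' \eqn{\epsilon_j = \sum_{i \ge j} \delta_i} (\eqn{\delta_i} the strain of
#' body i, counted from the wall side), so that the sensed strain is always
#' \eqn{\epsilon_{ne} = \epsilon_w - \epsilon_1}: the strain across the
#' series spring. In the per-body coordinates the dynamics are
#' \deqn{\dot\delta_i = \alpha_i (\epsilon_w - \epsilon_1)
#'       - (\beta_i - \alpha_i)\,\delta_i,}
#' which [chain_matrices()] transforms to the cumulative coordinates,
#' yielding a stable linear time-invariant system \eqn{\dot x = A x + b\,
#' \epsilon_w} whose poles are the n relaxation rates.
#'
#' @param n number of Voigt bodies (1, 2 or 3)
#' @param alpha rate coefficients \eqn{\alpha_i} (1/s), length `n`, > 0
#' @param beta rate coefficients \eqn{\beta_i} (1/s), length `n`, > 0 and
#'   pairwise distinct (distinct timescales)
#' @return an object of class `voigt_chain`
#' @examples
#' ch <- voigt_chain(2, alpha = c(0.5, 0.4), beta = c(0.5, 2))
#' relaxation_timescales(ch)
#' @export
voigt_chain <- function(n = 2, alpha, beta) {
  if (!n %in% 1:3) stop("voigt_chain supports n in {1, 2, 3}")
  if (missing(alpha)) alpha <- c(0.5, 0.4, 1)[seq_len(n)]
  if (missing(beta)) beta <- c(0.5, 2, 10)[seq_len(n)]
  stopifnot(length(alpha) == n, length(beta) == n,
            all(alpha > 0), all(beta > 0))
  if (n > 1 && min(abs(diff(sort(beta)))) == 0)
    warning("coincident beta values: timescales are not separated")
  structure(list(n = as.integer(n), alpha = as.numeric(alpha),
                 beta = as.numeric(beta)),
            class = "voigt_chain")
}

#' @export
print.voigt_chain <- function(x, ...) {
  cat(sprintf("<voigt chain: n = %d>\n  alpha: %s\n  beta:  %s\n", x$n,
              paste(signif(x$alpha, 4), collapse = ", "),
              paste(signif(x$beta, 4), collapse = ", ")))
  invisible(x)
}

#' Chain state-space matrices
#'
#' Returns the system matrix `A` and input vector `b` of the chain in the
#' cumulative-strain coordinates \eqn{\epsilon_1, ..., \epsilon_n}, such
#' that \eqn{\dot x = A x + b\,\epsilon_w}.
#'
#' @param chain a [voigt_chain()]
#' @return `list(A, b)`
#' @export
chain_matrices <- function(chain) {
  n <- chain$n
  a <- chain$alpha
  bd <- chain$beta - chain$alpha      # K_i / B_i
  # per-body coordinates: ddelta_i/dt = a_i (eps_w - eps_1) - bd_i delta_i,
  # with eps_1 = sum(delta). A_delta[i,j] = -a_i - bd_i [i==j]; b_delta = a.
  A_delta <- -outer(a, rep(1, n)) - diag(bd, n)
  # eps_j = sum_{i >= j} delta_i: S upper triangular of ones
  S <- matrix(as.numeric(row(diag(n)) <= col(diag(n))), n, n)
  A <- S %*% A_delta %*% solve(S)
  b <- drop(S %*% a)
  list(A = A, b = b)
}

#' Chain right-hand side
#'
#' Time derivative of the chain state at a given wall strain, i.e.
#' \eqn{A x + b\,\epsilon_w}. The wall strain enters as a value only; no
#' derivative of \eqn{\epsilon_w} appears in the mechanoreceptor dynamics.
#'
#' @param state chain state vector (cumulative strains), length `n`
#' @param eps_w wall strain (unitless scalar)
#' @param chain a [voigt_chain()]
#' @return derivative vector, length `n`
#' @export
chain_rhs <- function(state, eps_w, chain) {
  if (length(state) != chain$n)
    stop("state length ", length(state), " does not match n = ", chain$n)
  m <- chain_matrices(chain)
  drop(m$A %*% state) + m$b * eps_w
}

#' Nerve-ending strain
#'
#' The strain sensed by the mechanoreceptors:
#' \eqn{\epsilon_{ne} = \epsilon_w - \epsilon_1}, where \eqn{\epsilon_1} is
#' the first (cumulative) Voigt strain, i.e. the total strain taken up by
#' the Voigt bodies; what remains stretches the sensing spring.
#'
#' @param state chain state (vector of length n, or matrix with n columns)
#' @param eps_w wall strain (scalar or vector matching rows of `state`)
#' @return \eqn{\epsilon_{ne}} (unitless)
#' @export
nerve_ending_strain <- function(state, eps_w) {
  if (is.matrix(state)) eps_w - state[, 1] else eps_w - state[1]
}

#' Relaxation timescales of the chain
#'
#' Closed-form relaxation timescales \eqn{\tau_1 < ... < \tau_n} (s). The
#' characteristic polynomial of the chain has closed-form coefficients in
#' \eqn{(\alpha_i, \beta_i)}:
#' \deqn{n=1:\quad \lambda + \beta_1}
#' \deqn{n=2:\quad \lambda^2 + (\beta_1+\beta_2)\lambda +
#'   (\beta_1\beta_2 - \alpha_1\alpha_2)}
#' \deqn{n=3:\quad \lambda^3 + (\Sigma\beta_i)\lambda^2 +
#'   (\Sigma_{i<j}\beta_i\beta_j - \Sigma_{i<j}\alpha_i\alpha_j)\lambda +
#'   (\beta_1\beta_2\beta_3 - \Sigma_{i<j}\alpha_i\alpha_j\beta_k
#'    + 2\alpha_1\alpha_2\alpha_3)}
#' and the timescales are \eqn{\tau = -1/\lambda} for its roots, computed
#' here by the quadratic formula / trigonometric (Casus irreducibilis-safe)
#' cubic formula, independently of any numerical eigendecomposition. If the
#' roots are complex or non-positive the parameter regime is invalid and an
#' error is raised.
#'
#' @param chain a [voigt_chain()]
#' @return numeric vector of `n` timescales, ascending (s)
#' @export
relaxation_timescales <- function(chain) {
  a <- chain$alpha; b <- chain$beta
  lam <- switch(chain$n,
    -b[1],
    {
      B <- b[1] + b[2]
      C <- b[1] * b[2] - a[1] * a[2]
      disc <- B^2 - 4 * C
      if (disc < 0) stop("complex relaxation rates: invalid parameter regime")
      c((-B - sqrt(disc)) / 2, (-B + sqrt(disc)) / 2)
    },
    {
      c2 <- sum(b)
      c1 <- b[1] * b[2] + b[1] * b[3] + b[2] * b[3] -
        (a[1] * a[2] + a[1] * a[3] + a[2] * a[3])
      c0 <- prod(b) -
        (a[1] * a[2] * b[3] + a[1] * a[3] * b[2] + a[2] * a[3] * b[1]) +
        2 * prod(a)
      cubic_roots_real(c2, c1, c0)
    })
  if (any(lam >= 0)) stop("non-negative relaxation rate: unstable regime")
  sort(-1 / lam)
}

# real roots of x^3 + p2 x^2 + p1 x + p0 via the trigonometric method;
# errors out if roots are not all real (invalid chain regime)
cubic_roots_real <- function(p2, p1, p0) {
  q <- p1 / 3 - p2^2 / 9
  r <- (p1 * p2 - 3 * p0) / 6 - p2^3 / 27
  disc <- q^3 + r^2
  if (disc > 1e-12 * max(1, abs(q)^3, r^2))
    stop("complex relaxation rates: invalid parameter regime")
  m <- sqrt(pmax(-q, 0))
  if (m == 0) return(rep(-p2 / 3, 3))
  costh <- max(-1, min(1, r / m^3))
  th <- acos(costh)
  2 * m * cos((th + 2 * pi * (0:2)) / 3) - p2 / 3
}

#' Chain steady state
#'
#' State at which [chain_rhs()] vanishes for a constant wall strain:
#' the solution of \eqn{A x = -b\,\epsilon_w}. Linearity makes the steady
#' state homogeneous of degree one in \eqn{\epsilon_w}.
#'
#' @param chain a [voigt_chain()]
#' @param eps_w constant wall strain
#' @return steady chain state (length n)
#' @export
chain_steady_state <- function(chain, eps_w) {
  m <- chain_matrices(chain)
  drop(solve(m$A, -m$b * eps_w))
}

#' Static (DC) gain of the nerve-ending strain
#'
#' Fraction of a static wall strain transmitted to the nerve ending,
#' \eqn{\epsilon_{ne}^\infty / \epsilon_w = \prod_i (\beta_i - \alpha_i) /
#' c_0} with \eqn{c_0} the constant coefficient of the characteristic
#' polynomial. Strictly inside (0, 1) whenever all \eqn{\beta_i >
#' \alpha_i}; exactly 0 when any \eqn{\beta_i = \alpha_i} (complete
#' adaptation).
#'
#' @param chain a [voigt_chain()]
#' @return scalar DC gain
#' @export
chain_dc_gain <- function(chain) {
  ss <- chain_steady_state(chain, 1)
  1 - ss[1]
}
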