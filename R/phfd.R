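#' The power hazard function distribution
#'
#' Constructor for a validated parameter pair of the two-parameter power
#' hazard function distribution (PHFD), the lifetime model with hazard rate
#' \eqn{h(x) = \alpha x^\beta}.  Its survival function is
#' \eqn{S(x) = \exp\{-\alpha x^{\beta+1}/(\beta+1)\}} for \eqn{x > 0},
#' \eqn{\alpha > 0}, \eqn{\beta > -1}.
#'
#' Special cases: \eqn{\beta = 0} is the exponential distribution with rate
#' \eqn{\alpha}; \eqn{\beta = 1}, \eqn{\alpha = 1/\lambda^2} is
#' Rayleigh(\eqn{\lambda}); general \eqn{\beta} is a Weibull with shape
#' \eqn{\beta + 1}.  The hazard is increasing for \eqn{\beta > 0} and
#' decreasing for \eqn{-1 < \beta < 0}.
#'
#' @param alpha scale parameter, \eqn{\alpha > 0} (units time^-(beta+1)).
#' @param beta shape parameter, \eqn{\beta > -1} (dimensionless).
#' @return An object of class `"phfd"`: a list with elements `alpha` and
#'   `beta`.
#' @examples
#' p <- phfd(1.1835, 0.332)
#' mean(p)
#' phfd_sd(p)
#' @export
phfd <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha <= 0)
    stop("'alpha' must be strictly positive, got ", alpha)
  if (beta <= -1 + 1e-9)
    stop("'beta' must exceed -1 (guard band 1e-9), got ", beta)
  structure(list(alpha = alpha, beta = beta), class = "phfd")
}

#' @export
print.phfd <- function(x, ...) {
  cat(sprintf("PHFD(alpha = %g, beta = %g)\n", x$alpha, x$beta))
  invisible(x)
}

as_phfd <- function(params) {
  if (!inherits(params, "phfd"))
    stop("'params' must be a 'phfd' object; see phfd()")
  params
}

#' Moment constants of the power hazard distribution
#'
#' The two gamma-function constants that appear in every closed-form moment
#' and performance-index expression:
#' \eqn{\gamma_1 = \Gamma((\beta+2)/(\beta+1))} and
#' \eqn{\gamma_2 = \sqrt{\Gamma((\beta+3)/(\beta+1)) - \gamma_1^2}}.
#' The mean is \eqn{\gamma_1 (\alpha/(\beta+1))^{-1/(\beta+1)}} and the
#' standard deviation \eqn{\gamma_2 (\alpha/(\beta+1))^{-1/(\beta+1)}}, so
#' the ratio \eqn{\gamma_1/\gamma_2} is the supremum of the lifetime
#' performance index.
#'
#' @param beta shape parameter, \eqn{\beta > -1}.
#' @return A list with elements `beta`, `gamma1`, `gamma2`.
#' @examples
#' gamma_constants(0.332) # gamma1 = 0.9192, gamma2 = 0.6970 to 4 d.p.
#' @export
gamma_constants <- function(beta) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (beta <= -1 + 1e-9)
    stop("'beta' must exceed -1 (guard band 1e-9), got ", beta)
  bp1 <- beta + 1
  g1 <- exp(lgamma((beta + 2) / bp1))
  rad <- exp(lgamma((beta + 3) / bp1)) - g1^2
  if (rad < 0) {
    if (rad < -1e-12 * g1^2)
      stop("negative variance radicand beyond round-off at beta = ", beta)
    rad <- 0
  }
  list(beta = beta, gamma1 = g1, gamma2 = sqrt(rad))
}

#' Hazard rate of the power hazard distribution
#'
#' @param x vector of times, `x >= 0` (`x = 0` only allowed for
#'   `beta >= 0`).
#' @param params a [phfd()] object.
#' @return \eqn{\alpha x^\beta}, vectorised over `x`.
#' @export
hphfd <- function(x, params) {
  params <- as_phfd(params)
  if (any(x < 0)) stop("'x' must be nonnegative")
  if (params$beta < 0 && any(x == 0))
    stop("hazard at x = 0 is infinite for beta < 0")
  params$alpha * x^params$beta
}

# log of the survival function: -alpha * x^(beta+1) / (beta+1)
phfd_log_sf <- function(x, params) {
  bp1 <- params$beta + 1
  -params$alpha * x^bp1 / bp1
}

#' Distribution function of the power hazard distribution
#'
#' \eqn{F(x) = 1 - \exp\{-\alpha x^{\beta+1}/(\beta+1)\}}.
#'
#' @param q vector of nonnegative quantiles.
#' @inheritParams hphfd
#' @param lower.tail if `FALSE`, return the survival function, evaluated in
#'   log space so it does not underflow for large `q`.
#' @param log.p return log-probabilities.
#' @export
pphfd <- function(q, params, lower.tail = TRUE, log.p = FALSE) {
  params <- as_phfd(params)
  if (any(q < 0)) stop("'q' must be nonnegative")
  lsf <- phfd_log_sf(q, params)
  if (lower.tail) {
    p <- -expm1(lsf)  # 1 - exp(lsf), accurate when the cdf is tiny
    if (log.p) log(p) else p
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' Density of the power hazard distribution
#'
#' \eqn{f(x) = \alpha x^\beta \exp\{-\alpha x^{\beta+1}/(\beta+1)\}}, i.e.
#' hazard times survival.  At `x = 0` the density is 0 for `beta > 0`,
#' `alpha` for `beta = 0`, and `+Inf` for `beta < 0` (the density pole is
#' signalled, not an error).
#'
#' @param x vector of nonnegative times.
#' @inheritParams hphfd
#' @param log return the log-density.
#' @export
dphfd <- function(x, params, log = FALSE) {
  params <- as_phfd(params)
  if (any(x < 0)) stop("'x' must be nonnegative")
  a <- params$alpha; b <- params$beta
  ld <- ifelse(x > 0,
               log(a) + b * log(x) + phfd_log_sf(x, params),
               if (b > 0) -Inf else if (b == 0) log(a) else Inf)
  if (log) ld else exp(ld)
}

#' Quantile function of the power hazard distribution
#'
#' Analytic inverse of the distribution function:
#' \eqn{Q(u) = [-(\beta+1)\log(1-u)/\alpha]^{1/(\beta+1)}}.
#' `u = 1` maps to `Inf`.
#'
#' @param p vector of probabilities in `[0, 1]`.
#' @inheritParams hphfd
#' @export
qphfd <- function(p, params) {
  params <- as_phfd(params)
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
  bp1 <- params$beta + 1
  # -log1p(-p) is -log(1-p) computed stably near p -> 1
  (-bp1 * log1p(-p) / params$alpha)^(1 / bp1)
}

#' Random sampling from the power hazard distribution
#'
#' Inverse-transform sampling; deterministic under `set.seed()`.
#'
#' @param n number of draws, `n >= 1`.
#' @inheritParams hphfd
#' @export
rphfd <- function(n, params) {
  params <- as_phfd(params)
  stopifnot(length(n) == 1L, n >= 1)
  qphfd(stats::runif(n), params)
}

#' @describeIn phfd Mean lifetime
#'   \eqn{\gamma_1 (\alpha/(\beta+1))^{-1/(\beta+1)}}.
#' @param x,... a `"phfd"` object (for the `mean` method) and ignored extras.
#' @export
mean.phfd <- function(x, ...) {
  gc <- gamma_constants(x$beta)
  gc$gamma1 * phfd_scale(x)
}

# the characteristic time scale (alpha/(beta+1))^(-1/(beta+1))
phfd_scale <- function(params) {
  bp1 <- params$beta + 1
  (params$alpha / bp1)^(-1 / bp1)
}

#' Second raw moment of the power hazard distribution
#'
#' \eqn{E[X^2] = (\alpha/(\beta+1))^{-2/(\beta+1)}\Gamma((\beta+3)/(\beta+1))}.
#'
#' @inheritParams hphfd
#' @export
phfd_moment2 <- function(params) {
  params <- as_phfd(params)
  phfd_scale(params)^2 * exp(lgamma((params$beta + 3) / (params$beta + 1)))
}

#' Standard deviation of the power hazard distribution
#'
#' \eqn{\sigma = \gamma_2 (\alpha/(\beta+1))^{-1/(\beta+1)}}.
#'
#' @inheritParams hphfd
#' @export
phfd_sd <- function(params) {
  params <- as_phfd(params)
  gamma_constants(params$beta)$gamma2 * phfd_scale(params)
}
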