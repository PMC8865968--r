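#' Lifetime performance index
#'
#' The lifetime performance index (a process-capability index for lifetime
#' data) is \eqn{C_L = (\mu - L_X)/\sigma}, the standardised margin of the
#' mean lifetime over the lower specification limit \eqn{L_X}.  For the
#' power hazard distribution this is
#' \deqn{C_L = \frac{1}{\gamma_2}\left(\gamma_1 -
#'   (\alpha/(\beta+1))^{1/(\beta+1)} L_X\right),}
#' with \eqn{\gamma_1, \gamma_2} from [gamma_constants()].  `c_index` is
#' bounded above by \eqn{\gamma_1/\gamma_2} (attained at `l_x = 0`) and is
#' strictly decreasing in both `l_x` and `alpha`.
#'
#' @param params a [phfd()] object.
#' @param l_x lower specification limit, `l_x >= 0` (same time units as the
#'   lifetimes).
#' @return The index value (dimensionless).
#' @examples
#' p <- phfd(1.1835, 0.332)
#' c_index(p, mean(p))  # zero by construction
#' c_index(p, 0)        # upper limit gamma1/gamma2
#' @export
c_index <- function(params, l_x) {
  params <- as_phfd(params)
  stopifnot(is.numeric(l_x), all(l_x >= 0))
  gc <- gamma_constants(params$beta)
  (gc$gamma1 - l_x / phfd_scale(params)) / gc$gamma2
}

#' Conforming rate as a function of the performance index
#'
#' The conforming rate is \eqn{P_r = P(X \ge L_X)}, the probability that a
#' unit outlives the lower specification limit.  Writing \eqn{L_X} in terms
#' of \eqn{C_L}, the scale parameter cancels and
#' \deqn{P_r = \exp\{-(\gamma_1 - \gamma_2 C_L)^{\beta+1}\},}
#' a strictly increasing function of \eqn{C_L} on
#' \eqn{(-\infty, \gamma_1/\gamma_2]}.  When `alpha` is supplied the
#' survival function is instead evaluated in its unsimplified printed form
#' (with the \eqn{\alpha} factors present); the result is identical, which
#' doubles as a consistency check of the cancellation.
#'
#' Values of `c_l` above \eqn{\gamma_1/\gamma_2} are a hard error: they
#' correspond to a negative specification limit.
#'
#' @param c_l index value(s), each `<= gamma1/gamma2`.
#' @param beta known shape parameter.
#' @param alpha optional scale parameter; forces the unsimplified
#'   evaluation route.
#' @return Conforming probabilities in `[0, 1]`.
#' @examples
#' conforming_rate(0.90, 0.332)  # 0.823649
#' @export
conforming_rate <- function(c_l, beta, alpha = NULL) {
  gc <- gamma_constants(beta)
  if (any(c_l > gc$gamma1 / gc$gamma2 + 1e-12))
    stop("'c_l' exceeds the attainable maximum gamma1/gamma2 = ",
         signif(gc$gamma1 / gc$gamma2, 6))
  base <- pmax(gc$gamma1 - gc$gamma2 * c_l, 0)
  if (is.null(alpha)) {
    exp(-base^(beta + 1))
  } else {
    # as printed: S(L_X) at L_X = (alpha/(beta+1))^{-1/(beta+1)} * base
    stopifnot(alpha > 0)
    bp1 <- beta + 1
    l_x <- (alpha / bp1)^(-1 / bp1) * base
    exp(-alpha * l_x^bp1 / bp1)
  }
}

#' Invert the conforming-rate map
#'
#' Returns the index value whose conforming rate is `p_r`:
#' \eqn{C_L = (\gamma_1 - (-\log p_r)^{1/(\beta+1)})/\gamma_2}.
#'
#' @param p_r conforming probabilities in `(0, 1]`.
#' @param beta known shape parameter.
#' @export
c_from_rate <- function(p_r, beta) {
  if (any(p_r <= 0) || any(p_r > 1))
    stop("'p_r' must lie in (0, 1]")
  gc <- gamma_constants(beta)
  (gc$gamma1 - (-log(p_r))^(1 / (beta + 1))) / gc$gamma2
}

#' Specification limit attaining a given index value
#'
#' Inverse of [c_index()] in `l_x`:
#' \eqn{L_X = (\gamma_1 - \gamma_2 C_L)(\alpha/(\beta+1))^{-1/(\beta+1)}}.
#' Requires `c_l < gamma1/gamma2` (the limit is 0 at the supremum).
#'
#' @inheritParams c_index
#' @param c_l target index value.
#' @export
l_x_from_c <- function(params, c_l) {
  params <- as_phfd(params)
  gc <- gamma_constants(params$beta)
  if (any(c_l > gc$gamma1 / gc$gamma2))
    stop("'c_l' must not exceed gamma1/gamma2 = ",
         signif(gc$gamma1 / gc$gamma2, 6))
  (gc$gamma1 - gc$gamma2 * c_l) * phfd_scale(params)
}

#' Conforming-rate lookup table
#'
#' Tabulates the conforming rate over a grid of index values, in the layout
#' used to pick the required index level for a demanded conforming rate.
#'
#' @param beta known shape parameter.
#' @param c_l_grid numeric grid of index values (may be empty).
#' @param digits rounding applied to the displayed rate (default 6, the
#'   conventional presentation); the `p_r` column is rounded, `c_l` is not.
#' @return A data.frame with columns `c_l` and `p_r`.
#' @examples
#' rate_table(0.332, c(0, 0.90, 1.31))
#' @export
rate_table <- function(beta, c_l_grid, digits = 6) {
  if (length(c_l_grid) == 0L)
    return(data.frame(c_l = numeric(0), p_r = numeric(0)))
  data.frame(c_l = c_l_grid,
             p_r = round(conforming_rate(c_l_grid, beta), digits))
}
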