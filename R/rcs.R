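#' Restricted cubic spline basis
#'
#' The natural (restricted) cubic spline basis in the truncated-power form
#' used by Royston–Parmar survival models. For knots
#' \eqn{k_1 < \dots < k_K} the basis has \eqn{K - 1} columns (df = number of
#' knots minus one): the first is the identity \eqn{x}, and for each internal
#' knot \eqn{k_m} (\eqn{m = 2, \dots, K-1})
#' \deqn{v_m(x) = (x - k_m)_+^3 - \lambda_m (x - k_1)_+^3 -
#'   (1 - \lambda_m)(x - k_K)_+^3, \qquad
#'   \lambda_m = \frac{k_K - k_m}{k_K - k_1}.}
#' Each column is twice continuously differentiable and linear beyond the
#' boundary knots (second derivative zero outside \eqn{[k_1, k_K]}).
#'
#' @param knots strictly increasing numeric vector, length at least 2.
#' @return An object of class `rcs_basis`.
#' @export
rcs_basis <- function(knots) {
  if (length(knots) < 2) stop("need at least 2 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  structure(list(knots = as.numeric(knots), df = length(knots) - 1L),
            class = "rcs_basis")
}

#' Evaluate a restricted cubic spline basis
#'
#' @param basis an [rcs_basis()].
#' @param x numeric vector (for survival models, log time).
#' @param deriv if `TRUE`, return the first derivative of each basis column.
#' @return numeric matrix, `length(x)` rows by `basis$df` columns.
#' @examples
#' b <- rcs_basis(c(-1, 0, 1))
#' rcs_eval(b, c(-2, 0.5, 2))
#' @export
rcs_eval <- function(basis, x, deriv = FALSE) {
  stopifnot(inherits(basis, "rcs_basis"))
  k <- basis$knots
  K <- length(k)
  out <- matrix(0, length(x), K - 1L)
  out[, 1] <- if (deriv) 1 else x
  if (K > 2) {
    kmin <- k[1]
    kmax <- k[K]
    for (m in 2:(K - 1)) {
      lam <- (kmax - k[m]) / (kmax - kmin)
      if (deriv) {
        out[, m] <- 3 * (pmax(x - k[m], 0)^2 - lam * pmax(x - kmin, 0)^2 -
                           (1 - lam) * pmax(x - kmax, 0)^2)
      } else {
        out[, m] <- pmax(x - k[m], 0)^3 - lam * pmax(x - kmin, 0)^3 -
          (1 - lam) * pmax(x - kmax, 0)^3
      }
    }
  }
  out
}

#' Knot placement from event times
#'
#' The standard Royston–Parmar default: boundary knots at the minimum and
#' maximum of the log event times, internal knots at equally spaced centiles
#' (for df 3, the 33rd and 67th centiles).
#'
#' @param log_event_times log times of the uncensored observations.
#' @param df degrees of freedom (number of knots minus one), `>= 1`.
#' @return numeric vector of `df + 1` strictly increasing knots.
#' @export
rcs_knots <- function(log_event_times, df) {
  if (df < 1) stop("df must be at least 1")
  if (length(log_event_times) < df + 1)
    stop("too few events to place knots")
  probs <- seq(0, 1, length.out = df + 1)
  k <- unname(stats::quantile(log_event_times, probs = probs, type = 7))
  if (any(diff(k) <= 0))
    stop("degenerate knot placement (tied event-time centiles)")
  k
}
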