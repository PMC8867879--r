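#' Loss in life expectancy after a cancer diagnosis
#'
#' The loss in life expectancy (LLE) compares the remaining life expectancy
#' of a comparable cancer-free person with that of the patient, both
#' truncated at a horizon `t_max` at which survival is assumed to have
#' reached zero:
#' \deqn{LLE = \int_0^{t_{max}} S^*(t)\,dt -
#'       \int_0^{t_{max}} S^*(t) R(t)\,dt,}
#' where \eqn{S^*} is the expected survival from the life table and \eqn{R}
#' the (extrapolated) relative survival from the fitted model. The integrals
#' are evaluated by composite Gauss–Legendre quadrature on yearly panels,
#' matching the yearly step structure of \eqn{S^*}.
#'
#' @param fit an `rsfpm` fit, a [generating_fpm()], or a function
#'   `R(t)` returning relative survival at time `t`.
#' @param table a [lifetable()].
#' @param age_dx,year_dx age and calendar year at diagnosis (may be
#'   fractional).
#' @param t_max integration horizon in years; defaults to
#'   `age_cap - age_dx`, so extrapolation ends at the longest possible
#'   lifetime.
#' @param nodes Gauss–Legendre nodes per yearly panel (7 is accurate to well
#'   below 1e-6 years; doubling is a cheap convergence check).
#' @return `compute_lle()`: LLE in years. `compute_pll()`: the proportion of
#'   life lost, LLE divided by the cancer-free remaining life expectancy.
#' @examples
#' lt <- make_synthetic_lifetable(a = 1e-5, b = 0.09, years = 1900:2100)
#' compute_lle(function(t) rep(1, length(t)), lt, 60, 1970)  # R == 1 -> 0
#' @export
compute_lle <- function(fit, table, age_dx, year_dx,
                        t_max = table$age_cap - age_dx, nodes = 7) {
  lle_components(fit, table, age_dx, year_dx, t_max, nodes)$lle
}

#' @rdname compute_lle
#' @export
compute_pll <- function(fit, table, age_dx, year_dx,
                        t_max = table$age_cap - age_dx, nodes = 7) {
  cmp <- lle_components(fit, table, age_dx, year_dx, t_max, nodes)
  if (cmp$e_star <= 0) stop("zero cancer-free life expectancy denominator")
  cmp$lle / cmp$e_star
}

# Both integrals at once; e_star = cancer-free remaining life expectancy,
# e_obs = patient's remaining life expectancy, lle = difference.
lle_components <- function(fit, table, age_dx, year_dx, t_max, nodes = 7) {
  if (t_max <= 0) stop("t_max must be positive")
  if (age_dx + t_max > table$age_cap + 1e-9)
    stop("t_max extends beyond the life table's age cap")
  R_fun <- if (is.function(fit)) {
    fit
  } else if (inherits(fit, "rsfpm")) {
    function(t) predict_relative_survival(fit, age_dx, t)
  } else if (inherits(fit, "generating_fpm")) {
    function(t) gfpm_survival(fit, age_dx, t)
  } else stop("'fit' must be an rsfpm, generating_fpm or function of t")
  gl <- gauss_unit(nodes)
  # panel boundaries at every rate step of S*: crossings of integer attained
  # age and of integer calendar year during follow-up
  nxt <- function(x) floor(x) + 1 - x
  cuts <- c(nxt(age_dx) + 0:ceiling(t_max), nxt(year_dx) + 0:ceiling(t_max),
            # refined panels near t = 0, where the excess hazard of a
            # log-time spline model can be steep
            10^(-4:-1), 0.3)
  brk <- sort(unique(c(0, t_max, cuts[cuts < t_max])))
  lo <- brk[-length(brk)]
  len <- diff(brk)
  tq <- rep(lo, each = nodes) + rep(len, each = nodes) * gl$x
  wq <- rep(len, each = nodes) * gl$w
  Sstar <- expected_survival(table, age_dx, year_dx, tq)
  R <- R_fun(tq)
  e_star <- sum(wq * Sstar)
  e_obs <- sum(wq * Sstar * R)
  list(e_star = e_star, e_obs = e_obs, lle = e_star - e_obs)
}

# Gauss-Legendre nodes/weights on (0, 1), cached per node count.
gauss_unit <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      gl <- pracma::gaussLegendre(n, 0, 1)
      cache[[key]] <<- list(x = gl$x, w = gl$w)
    }
    cache[[key]]
  }
})

#' International Cancer Survival Standard age weights
#'
#' The ICSS reference age distribution used for external age
#' standardisation of cancer survival: proportions 7%, 12%, 23%, 29% and
#' 29% for age groups up to 44, 45–54, 55–64, 65–74 and 75 and above.
#'
#' @return data.frame with columns `lower`, `upper` (left-closed age
#'   intervals `[lower, upper)`) and `weight`.
#' @export
icss_weights <- function() {
  data.frame(lower = c(0, 45, 55, 65, 75),
             upper = c(45, 55, 65, 75, Inf),
             weight = c(0.07, 0.12, 0.23, 0.29, 0.29))
}

#' Marginal (standardised) estimates from individual predictions
#'
#' Averages individual predictions, optionally reweighted so the study age
#' mix matches an external reference distribution: each individual in age
#' group \eqn{g} gets weight \eqn{w_i = w^s_g / a_g}, the ratio of the
#' reference proportion to the sample proportion of the group, and the
#' estimate is \eqn{N^{-1} \sum_i w_i v_i}. With `ref = NULL` the plain mean
#' (internal standardisation to the sample age mix) is returned. Any
#' reference group with positive weight that is empty in the sample is an
#' error, not an extrapolation.
#'
#' @param values per-individual predictions (e.g. 10-year relative survival,
#'   LLE or PLL).
#' @param ages ages at diagnosis, required when `ref` is given.
#' @param ref reference age distribution as from [icss_weights()]
#'   (columns `lower`, `upper`, `weight`, weights summing to 1), or `NULL`.
#' @return the marginal estimate (scalar).
#' @export
standardize <- function(values, ages = NULL, ref = NULL) {
  if (length(values) == 0) stop("empty cohort")
  if (is.null(ref)) return(mean(values))
  if (is.null(ages) || length(ages) != length(values))
    stop("'ages' must accompany 'values' for external standardisation")
  if (abs(sum(ref$weight) - 1) > 1e-8)
    stop("reference weights must sum to 1")
  g <- findInterval(ages, ref$lower)
  if (any(g == 0)) stop("ages below the first reference group")
  counts <- tabulate(g, nbins = nrow(ref))
  if (any(ref$weight > 0 & counts == 0))
    stop("empty age group with positive reference weight")
  a <- counts / length(values)
  w <- ref$weight[g] / a[g]
  mean(w * values)
}
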