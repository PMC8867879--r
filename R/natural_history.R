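#' Natural-history parameters for the breast-cancer generator
#'
#' Bundles the parameters of the latent disease process: age-specific
#' per-year probabilities of tumour onset, the starting tumour diameter,
#' the distribution of individual growth rates, and the intensity of
#' size-driven symptomatic detection.
#'
#' The growth model is exponential in tumour volume: a tumour starting as a
#' sphere of diameter `d0` grows as \eqn{V(t) = V_0 e^{t/\tau}}, where the
#' inverse volume growth rate \eqn{\tau} (the volume e-folding time, in
#' years) is drawn per woman from a gamma distribution with shape
#' `tau_shape` and scale `tau_scale`. Symptomatic detection is the first
#' event of an inhomogeneous Poisson process with intensity
#' \eqn{\eta V(t)} (`eta`, per mm^3 per year): larger tumours surface
#' sooner. Each woman can develop at most one tumour.
#'
#' @param onset_ages,onset_probs integer ages and matching per-year onset
#'   probabilities (all in `[0, 1]`). Ages not listed have probability 0.
#' @param d0 tumour diameter at onset, mm.
#' @param tau_shape,tau_scale gamma shape and scale of the inverse volume
#'   growth rate \eqn{\tau} (years).
#' @param eta symptomatic-detection intensity per mm^3 of tumour volume per
#'   year; `>= 0`.
#' @param cohort_size women per birth-year cohort.
#' @param birth_years integer vector of birth years.
#' @return An object of class `nh_params`.
#' @seealso [default_onset_probs()], [simulate_latent_population()]
#' @export
natural_history_params <- function(onset_ages, onset_probs,
                                   d0 = 0.5,
                                   tau_shape = 1.3, tau_scale = 0.7,
                                   eta = 3e-4,
                                   cohort_size = 10000,
                                   birth_years = 1870:1965) {
  if (length(onset_ages) != length(onset_probs))
    stop("onset_ages and onset_probs must have equal length")
  if (any(onset_probs < 0 | onset_probs > 1))
    stop("onset probabilities must lie in [0, 1]")
  if (d0 <= 0) stop("'d0' must be positive")
  if (tau_shape <= 0 || tau_scale <= 0) stop("gamma parameters must be positive")
  if (eta < 0) stop("'eta' must be non-negative")
  if (cohort_size <= 0) stop("'cohort_size' must be positive")
  structure(
    list(onset_ages = as.integer(onset_ages), onset_probs = onset_probs,
         d0 = d0, tau_shape = tau_shape, tau_scale = tau_scale, eta = eta,
         cohort_size = as.integer(cohort_size),
         birth_years = as.integer(birth_years)),
    class = "nh_params"
  )
}

#' Default age-specific tumour onset probabilities
#'
#' A smooth unimodal stand-in curve for the per-year probability of breast
#' tumour onset: zero before age 25, then a Gaussian-shaped bump
#' \eqn{p(a) = p_{max} \exp(-((a - a_{peak}) / w)^2)}. The defaults were
#' calibrated once, qualitatively, so that without screening the median age
#' at symptomatic diagnosis is about 62, most diagnosed tumours are below
#' 32.5 mm, and a 96-cohort population yields on the order of a few thousand
#' diagnoses in a five-year window per 10,000-women cohorts.
#'
#' @param ages integer ages to tabulate.
#' @param p_max peak per-year onset probability.
#' @param a_peak age of peak onset.
#' @param w width (years) of the bump.
#' @param a_min no onset below this age.
#' @return data.frame with columns `age` and `prob`.
#' @export
default_onset_probs <- function(ages = 0:100, p_max = 0.0028, a_peak = 59,
                                w = 19, a_min = 25) {
  prob <- ifelse(ages >= a_min, p_max * exp(-((ages - a_peak) / w)^2), 0)
  data.frame(age = as.integer(ages), prob = prob)
}

#' Simulate tumour onset ages
#'
#' For each woman, integer ages are scanned in increasing order; the first
#' Bernoulli success at age `a` (probability `onset_probs[a]`) places tumour
#' onset uniformly within `[a, a + 1)`. At most one onset per woman, ever.
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param params an [natural_history_params()] object.
#' @param n number of women.
#' @return numeric vector of onset ages (`NA` for women without onset).
#' @export
simulate_onset <- function(params, n) {
  stopifnot(inherits(params, "nh_params"))
  onset <- rep(NA_real_, n)
  keep <- which(params$onset_probs > 0)
  for (j in keep[order(params$onset_ages[keep])]) {
    idx <- which(is.na(onset))
    if (length(idx) == 0) break
    hit <- stats::runif(length(idx)) < params$onset_probs[j]
    if (any(hit))
      onset[idx[hit]] <- params$onset_ages[j] + stats::runif(sum(hit))
  }
  onset
}

#' Tumour diameter at a given age
#'
#' Under exponential volume growth the diameter of a spherical tumour is
#' \eqn{d(t) = d_0 \exp(t / (3\tau))} with \eqn{t} the time since onset:
#' the volume e-folds every \eqn{\tau} years, so the diameter e-folds every
#' \eqn{3\tau} years.
#'
#' @param onset_age onset age(s), years.
#' @param tau inverse volume growth rate(s), years.
#' @param d0 diameter at onset, mm.
#' @param age age(s) at which to evaluate, `>= onset_age`.
#' @return diameter(s) in mm.
#' @export
tumour_diameter <- function(onset_age, tau, d0, age) {
  if (any(age < onset_age)) stop("age before tumour onset")
  d0 * exp((age - onset_age) / (3 * tau))
}

#' Simulate the latent symptomatic detection age
#'
#' The first event time of a Poisson process with intensity
#' \eqn{\eta V(u) = \eta V_0 e^{(u - a_{onset})/\tau}} solves
#' \eqn{\eta V_0 \tau (e^{t/\tau} - 1) = E} with \eqn{E \sim Exp(1)},
#' giving the closed form \eqn{t = \tau \log(1 + E / (\eta V_0 \tau))}.
#' Detection ages beyond `age_cap` are returned as `NA` (the tumour never
#' surfaces within the longest possible lifetime); `eta = 0` never detects.
#' Uses the current RNG state.
#'
#' @inheritParams tumour_diameter
#' @param eta detection intensity per mm^3 per year.
#' @param age_cap longest possible lifetime (years).
#' @param E optional vector of unit-exponential draws (for testing); defaults
#'   to fresh draws.
#' @return latent symptomatic ages (`NA` if never detected before the cap).
#' @export
simulate_symptomatic_age <- function(onset_age, tau, d0, eta, age_cap = 100,
                                     E = NULL) {
  if (eta < 0) stop("'eta' must be non-negative")
  n <- length(onset_age)
  if (is.null(E)) E <- stats::rexp(n)
  if (eta == 0) return(rep(NA_real_, n))
  V0 <- pi / 6 * d0^3
  t <- tau * log1p(E / (eta * V0 * tau))
  age <- onset_age + t
  age[age > age_cap] <- NA_real_
  age
}

#' Simulate a latent population with scenario-invariant deaths
#'
#' Generates the complete counterfactual record of every woman with tumour
#' onset: birth cohort, onset age, individual growth rate, latent symptomatic
#' age, cancer and other-cause death ages, and the pre-drawn screening
#' randomness (attendance type, per-visit attendance and detection uniforms)
#' that makes screening scenarios comparable on identical latent data.
#' Death is the minimum of the cancer and other-cause components and is fixed
#' before any screening is imposed, so it is identical across scenarios by
#' construction; screening can only move the diagnosis date.
#'
#' Cancer death times are measured from the latent symptomatic age (the
#' clock origin of the generating relative-survival model), so women whose
#' tumour would never surface before the age cap receive no cancer-death
#' draw. Stage-specific RNG substreams are derived from `seed` so that each
#' simulation stage (onset, growth, detection, other-cause death, cancer
#' death, screening randomness) is reproducible in isolation.
#'
#' @param params an [natural_history_params()] object.
#' @param table a [lifetable()] covering `birth_years` through
#'   `max(birth_years) + age_cap`.
#' @param model a [generating_fpm()] for cancer death times.
#' @param seed integer seed for the replicate.
#' @param n_visits number of screening visits for which randomness is
#'   pre-drawn (defaults to 18: biennial ages 40-74).
#' @return An object of class `latent_population`: a list with `women`
#'   (data.frame of onset women), `n_total`, and `screening_u` (pre-drawn
#'   uniforms).
#' @export
simulate_latent_population <- function(params, table, model, seed,
                                       n_visits = 18L) {
  stopifnot(inherits(params, "nh_params"), inherits(table, "lifetable"),
            inherits(model, "generating_fpm"))
  n_total <- params$cohort_size * length(params$birth_years)
  birth_year <- rep(params$birth_years, each = params$cohort_size)
  age_cap <- table$age_cap

  set.seed(stage_seed(seed, 1L))
  onset <- simulate_onset(params, n_total)
  has <- which(!is.na(onset))
  women <- data.frame(id = has,
                      birth_year = birth_year[has],
                      onset_age = onset[has])
  n <- nrow(women)
  women$tau <- stats::rgamma(n, shape = params$tau_shape,
                             scale = params$tau_scale)

  set.seed(stage_seed(seed, 2L))
  women$sympt_age <- simulate_symptomatic_age(
    women$onset_age, women$tau, params$d0, params$eta, age_cap = age_cap)

  set.seed(stage_seed(seed, 3L))
  women$other_death_age <- simulate_other_cause_death(
    table, women$birth_year, age_cap = age_cap)

  set.seed(stage_seed(seed, 4L))
  women$cancer_death_age <- rep(NA_real_, n)
  idx <- which(!is.na(women$sympt_age))
  if (length(idx)) {
    tt <- simulate_cancer_death_time(
      model, age_dx = women$sympt_age[idx],
      horizon = age_cap - women$sympt_age[idx])
    women$cancer_death_age[idx] <- women$sympt_age[idx] + tt
  }
  dr <- resolve_death(women$cancer_death_age, women$other_death_age)
  women$death_age <- dr$death_age
  women$cause <- dr$cause

  set.seed(stage_seed(seed, 5L))
  screening_u <- list(
    type = stats::runif(n),
    attend = matrix(stats::runif(n * n_visits), n, n_visits),
    detect = matrix(stats::runif(n * n_visits), n, n_visits)
  )

  structure(list(women = women, n_total = n_total, params = params,
                 age_cap = age_cap, screening_u = screening_u, seed = seed),
            class = "latent_population")
}

#' @export
print.latent_population <- function(x, ...) {
  cat("Latent population:", x$n_total, "women,",
      nrow(x$women), "with tumour onset\n")
  cat("  birth years:", min(x$params$birth_years), "-",
      max(x$params$birth_years), "\n")
  cat("  latent symptomatic before cap:",
      sum(!is.na(x$women$sympt_age)), "\n")
  invisible(x)
}

# Derive a 32-bit substream seed for stage k of replicate `seed`.
stage_seed <- function(seed, k) {
  as.integer(((as.double(seed) + 97 * as.double(k)) * 7919 + 104729) %%
               2147483647)
}
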