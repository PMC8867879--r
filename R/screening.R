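#' Define a screening programme
#'
#' A biennial invitation schedule (by default ages 40, 42, ..., 74 — 18
#' visits, age-anchored per woman), a logistic size-dependent test
#' sensitivity, and an attendance model: `"perfect"` (everyone attends every
#' visit) or `"imperfect"` (a fraction `frac_high` of women attend each
#' visit with probability `p_high`, the rest with `p_low`).
#'
#' @param beta1,beta2 logistic sensitivity intercept and slope per mm of
#'   tumour diameter; see [screening_sensitivity()].
#' @param attendance `"perfect"` or `"imperfect"`.
#' @param age_first,age_last,interval invitation schedule (years).
#' @param frac_high,p_high,p_low imperfect-attendance mixture: fraction of
#'   high attenders and the per-visit attendance probabilities of the two
#'   types (defaults 80% attending with probability 0.9, 20% with 0.15).
#' @return An object of class `screening_programme` with a `visits` field.
#' @export
screening_programme <- function(beta1, beta2,
                                attendance = c("perfect", "imperfect"),
                                age_first = 40, age_last = 74, interval = 2,
                                frac_high = 0.8, p_high = 0.9, p_low = 0.15) {
  attendance <- match.arg(attendance)
  visits <- seq(age_first, age_last, by = interval)
  if (!(p_low >= 0 && p_low < p_high && p_high <= 1))
    stop("need 0 <= p_low < p_high <= 1")
  if (frac_high < 0 || frac_high > 1) stop("frac_high must lie in [0, 1]")
  structure(list(beta1 = beta1, beta2 = beta2, attendance = attendance,
                 visits = visits, frac_high = frac_high,
                 p_high = p_high, p_low = p_low),
            class = "screening_programme")
}

#' Screening sensitivity scenarios
#'
#' The three logistic sensitivity parameter pairs studied: low
#' (`beta1 = -5.45`, `beta2 = 0.48`), moderate (`-5.04`, `0.56`) and high
#' (`-4.67`, `0.65`), giving sensitivities of 0.58, 0.84 and 0.96 for a
#' 12 mm tumour.
#'
#' @return named list of `c(beta1, beta2)` pairs.
#' @export
sensitivity_scenarios <- function() {
  list(low = c(beta1 = -5.45, beta2 = 0.48),
       moderate = c(beta1 = -5.04, beta2 = 0.56),
       high = c(beta1 = -4.67, beta2 = 0.65))
}

#' Size-dependent screening sensitivity
#'
#' The probability that a tumour of diameter `d` mm is detected at an
#' attended screen: \eqn{expit(\beta_1 + \beta_2 d)}, computed
#' overflow-safely.
#'
#' @param d tumour diameter, mm.
#' @param beta1,beta2 logistic intercept and slope.
#' @return detection probability.
#' @examples
#' screening_sensitivity(12, -5.04, 0.56)  # about 0.84
#' @export
screening_sensitivity <- function(d, beta1, beta2) {
  if (any(d < 0)) stop("diameter must be non-negative")
  stats::plogis(beta1 + beta2 * d)
}

#' Simulate attendance at screening visits
#'
#' Perfect attendance sets every flag; imperfect attendance first assigns
#' each woman an attender type (high with probability `frac_high`), then
#' draws independent per-visit Bernoulli flags with her type's probability.
#' `attendance_from_uniforms()` applies the same rule to pre-drawn uniforms,
#' which lets screening scenarios that share a latent population reuse
#' identical randomness.
#'
#' @param programme a [screening_programme()].
#' @param n_women number of women.
#' @return logical matrix, `n_women` by `length(visits)`.
#' @export
simulate_attendance <- function(programme, n_women) {
  nv <- length(programme$visits)
  attendance_from_uniforms(programme, stats::runif(n_women),
                           matrix(stats::runif(n_women * nv), n_women, nv))
}

#' @rdname simulate_attendance
#' @param type_u per-woman uniforms deciding attender type.
#' @param visit_u per-woman, per-visit uniforms.
#' @export
attendance_from_uniforms <- function(programme, type_u, visit_u) {
  stopifnot(inherits(programme, "screening_programme"))
  nv <- length(programme$visits)
  if (ncol(visit_u) < nv) stop("too few pre-drawn visit uniforms")
  visit_u <- visit_u[, seq_len(nv), drop = FALSE]
  if (programme$attendance == "perfect")
    return(matrix(TRUE, nrow(visit_u), nv))
  p <- ifelse(type_u < programme$frac_high, programme$p_high, programme$p_low)
  visit_u < p
}

#' Impose a screening programme on fixed latent histories
#'
#' Scans each woman's attended visits in age order, restricted to visits
#' strictly after tumour onset and strictly before
#' `min(latent symptomatic age, death age)`. At each such visit the tumour
#' (diameter from the growth model at the visit age) is detected with the
#' size-dependent sensitivity; the first success yields a screen diagnosis
#' with lead time `latent symptomatic age - visit age`. Without a screen
#' detection, a symptomatic diagnosis occurs at the latent symptomatic age
#' if that precedes death; otherwise the woman is never diagnosed. The
#' no-screening scenario is the special case of no attended visits.
#'
#' Death ages are inputs and are never altered: screening moves diagnosis,
#' not death. Lead time is 0 for symptomatic diagnoses; for screen
#' detections whose latent symptomatic age lies beyond the death age the
#' lead time still uses the latent age when it exists (`NA` only when the
#' tumour would never have surfaced before the age cap — flagged by
#' `latent_beyond_death` rather than hidden).
#'
#' @param histories data.frame with columns `id`, `birth_year`, `onset_age`,
#'   `tau`, `sympt_age` (NA if never symptomatic before the cap) and
#'   `death_age`.
#' @param programme a [screening_programme()].
#' @param attend logical attendance matrix (rows = women, columns = visits),
#'   e.g. from [simulate_attendance()]; ignored columns beyond the
#'   programme's visits are dropped.
#' @param detect_u matrix of per-visit detection uniforms; defaults to fresh
#'   draws.
#' @param d0 tumour diameter at onset, mm.
#' @return data.frame of diagnosed women: `id`, `mode`
#'   (`"screen"`/`"symptomatic"`), `dx_age`, `dx_year`, `diameter`,
#'   `lead_time`, `death_age`, `latent_beyond_death`.
#' @export
impose_screening <- function(histories, programme, attend = NULL,
                             detect_u = NULL, d0 = 0.5) {
  stopifnot(inherits(programme, "screening_programme"))
  n <- nrow(histories)
  visits <- programme$visits
  nv <- length(visits)
  if (is.null(attend)) attend <- matrix(FALSE, n, nv)
  attend <- attend[, seq_len(nv), drop = FALSE]
  if (is.null(detect_u))
    detect_u <- matrix(stats::runif(n * nv), n, nv)
  detect_u <- detect_u[, seq_len(nv), drop = FALSE]

  sympt <- ifelse(is.na(histories$sympt_age), Inf, histories$sympt_age)
  limit <- pmin(sympt, histories$death_age)
  V <- matrix(visits, n, nv, byrow = TRUE)
  eligible <- attend & (V > histories$onset_age) & (V < limit)
  diam <- matrix(0, n, nv)
  if (any(eligible)) {
    diam[eligible] <- d0 *
      exp((V[eligible] - rep(histories$onset_age, nv)[eligible]) /
            (3 * rep(histories$tau, nv)[eligible]))
  }
  detected <- eligible &
    detect_u < screening_sensitivity(diam, programme$beta1, programme$beta2)
  any_det <- rowSums(detected) > 0
  first <- integer(n)
  first[any_det] <- max.col(detected[any_det, , drop = FALSE],
                            ties.method = "first")

  scr <- which(any_det)
  sym <- which(!any_det & sympt < histories$death_age)

  rec <- function(i, mode, dx_age, diameter, lead) {
    data.frame(id = histories$id[i], mode = mode, dx_age = dx_age,
               dx_year = histories$birth_year[i] + dx_age,
               diameter = diameter, lead_time = lead,
               death_age = histories$death_age[i],
               latent_beyond_death =
                 !is.na(histories$sympt_age[i]) &
                   histories$sympt_age[i] > histories$death_age[i])
  }
  out <- list()
  if (length(scr)) {
    v <- visits[first[scr]]
    out$screen <- rec(
      scr, "screen", v,
      diam[cbind(scr, first[scr])],
      ifelse(is.na(histories$sympt_age[scr]), NA_real_,
             histories$sympt_age[scr] - v))
  }
  if (length(sym)) {
    dxa <- histories$sympt_age[sym]
    out$sympt <- rec(
      sym, "symptomatic", dxa,
      tumour_diameter(histories$onset_age[sym], histories$tau[sym], d0, dxa),
      0)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(id = integer(0), mode = character(0),
                      dx_age = numeric(0), dx_year = numeric(0),
                      diameter = numeric(0), lead_time = numeric(0),
                      death_age = numeric(0),
                      latent_beyond_death = logical(0))
  }
  rownames(res) <- NULL
  res[order(res$id), , drop = FALSE]
}

#' Follow-up and event indicator under administrative censoring
#'
#' Follow-up runs from diagnosis until death or `censor_years` after
#' diagnosis, whichever comes first; the event indicator is 1 exactly when
#' death precedes the censoring time (`death - diagnosis < censor_years`;
#' a death at exactly the censoring boundary is censored).
#'
#' @param dx_age age at diagnosis.
#' @param death_age age at death, `>= dx_age`.
#' @param censor_years administrative censoring horizon (default 12).
#' @return data.frame with columns `fu` and `event`.
#' @export
make_record <- function(dx_age, death_age, censor_years = 12) {
  if (any(death_age < dx_age)) stop("negative follow-up")
  fu <- pmin(death_age - dx_age, censor_years)
  data.frame(fu = fu, event = as.integer(death_age - dx_age < censor_years))
}
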