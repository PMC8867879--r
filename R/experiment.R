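#' Default simulation-study configuration
#'
#' Bundles every parameter of the study: the synthetic life table, the
#' natural-history generator, the generating relative-survival model, the
#' screening scenario grid, and the estimation settings (diagnosis window
#' 1970–1974, 12-year administrative censoring, df-3 baseline with a df-3
#' time-dependent age effect, ICSS external weights). The full-scale profile
#' mirrors the study design (96 birth cohorts of 10,000 women, 200
#' replicates); `fast = TRUE` is a desk-scale profile (500 women per cohort,
#' 20 replicates) that preserves every structural setting.
#'
#' @param fast use the reduced desk-scale profile.
#' @return a nested configuration list.
#' @export
default_config <- function(fast = FALSE) {
  op <- default_onset_probs()
  list(
    lifetable = list(a = 5e-5, b = 0.09, c = 1.5e-3, drift = 0.998,
                     reference_year = 1950, years = 1870:2066,
                     age_cap = 100),
    natural_history = list(onset_ages = op$age, onset_probs = op$prob,
                           d0 = 0.5, tau_shape = 1.3, tau_scale = 0.7,
                           eta = 3e-4,
                           cohort_size = if (fast) 500L else 10000L,
                           birth_years = 1870:1965),
    generating_fpm = default_generating_fpm(),
    screening = list(sensitivities = sensitivity_scenarios(),
                     attendances = c("perfect", "imperfect"),
                     age_first = 40, age_last = 74, interval = 2,
                     frac_high = 0.8, p_high = 0.9, p_low = 0.15),
    estimation = list(window = c(1970, 1974), censor_years = 12,
                      df_baseline = 3, df_tvc = 3,
                      ref = icss_weights(), min_events = 15),
    experiment = list(n_reps = if (fast) 20L else 200L)
  )
}

#' Read a configuration file
#'
#' Reads a YAML configuration with any of the blocks `lifetable`,
#' `natural_history`, `generating_fpm`, `screening`, `estimation` and
#' `experiment`, and merges it over [default_config()]: settings present in
#' the file override the defaults, everything else is inherited. A
#' `generating_fpm` block must provide `knots`, `gamma`, `alpha` and
#' optionally `age_center`.
#'
#' @param path path to a YAML file.
#' @param fast base profile to merge into (see [default_config()]).
#' @return a configuration list.
#' @export
read_config <- function(path, fast = FALSE) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the 'yaml' package")
  user <- yaml::read_yaml(path)
  cfg <- default_config(fast = fast)
  for (block in intersect(names(user), names(cfg))) {
    if (block == "generating_fpm") {
      g <- user[[block]]
      cfg$generating_fpm <- generating_fpm(
        knots = g$knots, gamma = g$gamma, alpha = g$alpha,
        age_center = if (is.null(g$age_center)) 0 else g$age_center)
    } else {
      cfg[[block]] <- utils::modifyList(cfg[[block]], user[[block]])
    }
  }
  cfg
}

# Materialise the life table and natural-history objects once per run.
config_objects <- function(config) {
  ltc <- config$lifetable
  lt <- make_synthetic_lifetable(a = ltc$a, b = ltc$b, c = ltc$c,
                                 drift = ltc$drift, years = ltc$years,
                                 age_cap = ltc$age_cap,
                                 reference_year = ltc$reference_year)
  nhc <- config$natural_history
  nh <- natural_history_params(onset_ages = nhc$onset_ages,
                               onset_probs = nhc$onset_probs, d0 = nhc$d0,
                               tau_shape = nhc$tau_shape,
                               tau_scale = nhc$tau_scale, eta = nhc$eta,
                               cohort_size = nhc$cohort_size,
                               birth_years = nhc$birth_years)
  list(lifetable = lt, nh = nh, gfpm = config$generating_fpm)
}

# The seven scenarios: no screening plus sensitivity x attendance grid.
scenario_grid <- function(config) {
  sc <- config$screening
  grid <- expand.grid(sensitivity = names(sc$sensitivities),
                      attendance = sc$attendances,
                      stringsAsFactors = FALSE)
  rbind(data.frame(scenario = "none", sensitivity = NA_character_,
                   attendance = NA_character_),
        data.frame(scenario = paste(grid$sensitivity, grid$attendance,
                                    sep = "_"),
                   sensitivity = grid$sensitivity,
                   attendance = grid$attendance))
}

#' Run one simulation replicate across all screening scenarios
#'
#' Generates one latent population (onset, growth, latent symptomatic age,
#' and scenario-invariant death ages), then for each scenario — no screening
#' plus the sensitivity-by-attendance grid — imposes the screening
#' programme on the *same* latent data, keeps diagnoses whose calendar year
#' falls in the configured window, applies administrative censoring, fits
#' the relative-survival FPM, and computes externally standardised 10-year
#' relative survival, LLE and PLL together with cohort descriptives and
#' lead-time summaries. Scenarios with too few events are reported with
#' `NA` estimates and a message rather than an error.
#'
#' @param config a configuration list as from [default_config()].
#' @param seed integer replicate seed (drives every stage substream).
#' @param objects optional pre-built result of the internal constructors
#'   (life table etc.); built from `config` when `NULL`.
#' @param keep_records also return the per-scenario diagnosis records
#'   (window-restricted) for auditing.
#' @return a data.frame of per-scenario estimates (one row per scenario);
#'   with `keep_records = TRUE`, a list with elements `estimates`,
#'   `records` and `population`.
#' @export
run_replicate <- function(config, seed, objects = NULL,
                          keep_records = FALSE) {
  if (is.null(objects)) objects <- config_objects(config)
  sc <- config$screening
  est <- config$estimation
  pop <- simulate_latent_population(objects$nh, objects$lifetable,
                                    objects$gfpm, seed,
                                    n_visits = length(seq(sc$age_first,
                                                          sc$age_last,
                                                          sc$interval)))
  grid <- scenario_grid(config)
  rows <- vector("list", nrow(grid))
  recs <- if (keep_records) vector("list", nrow(grid)) else NULL
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (g$scenario == "none") {
      prog <- screening_programme(beta1 = -Inf, beta2 = 0,
                                  attendance = "perfect",
                                  age_first = sc$age_first,
                                  age_last = sc$age_last,
                                  interval = sc$interval)
      attend <- NULL  # no visits attended: pure symptomatic scenario
    } else {
      betas <- sc$sensitivities[[g$sensitivity]]
      prog <- screening_programme(beta1 = betas[["beta1"]],
                                  beta2 = betas[["beta2"]],
                                  attendance = g$attendance,
                                  age_first = sc$age_first,
                                  age_last = sc$age_last,
                                  interval = sc$interval,
                                  frac_high = sc$frac_high,
                                  p_high = sc$p_high, p_low = sc$p_low)
      attend <- attendance_from_uniforms(prog, pop$screening_u$type,
                                         pop$screening_u$attend)
    }
    records <- impose_screening(pop$women, prog, attend = attend,
                                detect_u = pop$screening_u$detect,
                                d0 = objects$nh$d0)
    records <- records[floor(records$dx_year) >= est$window[1] &
                         floor(records$dx_year) <= est$window[2], ,
                       drop = FALSE]
    fe <- make_record(records$dx_age, records$death_age,
                      censor_years = est$censor_years)
    records$fu <- fe$fu
    records$event <- fe$event
    if (keep_records) recs[[i]] <- records
    rows[[i]] <- cbind(data.frame(seed = seed, scenario = g$scenario,
                                  sensitivity = g$sensitivity,
                                  attendance = g$attendance),
                       estimate_scenario(records, objects$lifetable, est))
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  if (keep_records) {
    names(recs) <- grid$scenario
    list(estimates = estimates, records = recs, population = pop)
  } else estimates
}

# Fit the FPM and compute standardized metrics plus descriptives for one
# scenario's window-restricted records.
estimate_scenario <- function(records, table, est) {
  desc <- summarize_cohort(records)
  lead <- lead_time_summary(records)
  out <- cbind(desc, lead, rs10 = NA_real_, lle = NA_real_, pll = NA_real_,
               fit_ok = FALSE)
  if (nrow(records) == 0 || sum(records$event) < est$min_events) {
    message("scenario skipped: only ", if (nrow(records)) sum(records$event)
            else 0, " events")
    return(out)
  }
  # expected rate at the exit time, by attained age and calendar year;
  # the open age group's infinite rate is replaced by the last closed
  # age group's rate so the likelihood stays finite for deaths at the cap
  exit_age <- pmin(records$dx_age + records$fu, table$age_cap - 1)
  exit_year <- records$dx_year + records$fu
  hstar <- lifetable_rate(table, exit_age, exit_year)
  fit <- tryCatch(
    fit_relative_survival_fpm(records$fu, records$event, records$dx_age,
                              expected_rate = hstar,
                              df_baseline = est$df_baseline,
                              df_tvc = est$df_tvc),
    error = function(e) {
      message("scenario skipped: ", conditionMessage(e))
      NULL
    })
  if (is.null(fit)) return(out)
  n <- nrow(records)
  rs10_i <- predict_relative_survival(fit, records$dx_age, rep(10, n))
  lle_i <- pll_i <- numeric(n)
  for (j in seq_len(n)) {
    cmp <- lle_components(
      function(t) predict_relative_survival(fit, records$dx_age[j], t),
      table, records$dx_age[j], records$dx_year[j],
      t_max = table$age_cap - records$dx_age[j])
    lle_i[j] <- cmp$lle
    pll_i[j] <- cmp$lle / cmp$e_star
  }
  std <- tryCatch(
    list(rs10 = standardize(rs10_i, records$dx_age, est$ref),
         lle = standardize(lle_i, records$dx_age, est$ref),
         pll = standardize(pll_i, records$dx_age, est$ref)),
    error = function(e) {
      message("scenario skipped: ", conditionMessage(e))
      NULL
    })
  if (is.null(std)) return(out)
  out$rs10 <- std$rs10
  out$lle <- std$lle
  out$pll <- std$pll
  out$fit_ok <- TRUE
  out
}

#' Cohort descriptives for a diagnosed cohort
#'
#' Number diagnosed; mean, 25th percentile, median and 75th percentile of
#' age at diagnosis; percentage dead within the administrative censoring
#' horizon; and the percentage shares of tumour diameter at diagnosis in the
#' four conventional bins below 17.5 mm, 17.5–32.5 mm, 32.5–47.5 mm and
#' above 47.5 mm (left-closed at the printed cut points: a 17.5 mm tumour
#' falls in 17.5–32.5).
#'
#' @param records a diagnosis-record data.frame with columns `dx_age`,
#'   `diameter` and `event`.
#' @return one-row data.frame of descriptives.
#' @export
summarize_cohort <- function(records) {
  n <- nrow(records)
  if (n == 0) {
    return(data.frame(n = 0L, mean_age = NA_real_, age_p25 = NA_real_,
                      median_age = NA_real_, age_p75 = NA_real_,
                      pct_dead = NA_real_, pct_size_lt17.5 = NA_real_,
                      pct_size_17.5_32.5 = NA_real_,
                      pct_size_32.5_47.5 = NA_real_,
                      pct_size_gt47.5 = NA_real_))
  }
  q <- stats::quantile(records$dx_age, c(0.25, 0.5, 0.75), names = FALSE)
  bins <- cut(records$diameter, c(-Inf, 17.5, 32.5, 47.5, Inf),
              right = FALSE)
  share <- 100 * as.numeric(table(bins)) / n
  data.frame(n = n, mean_age = mean(records$dx_age), age_p25 = q[1],
             median_age = q[2], age_p75 = q[3],
             pct_dead = 100 * mean(records$event),
             pct_size_lt17.5 = share[1], pct_size_17.5_32.5 = share[2],
             pct_size_32.5_47.5 = share[3], pct_size_gt47.5 = share[4])
}

#' Screen-detection and lead-time summaries
#'
#' Percentage screen-detected in the diagnosed cohort (overall and among
#' diagnoses at the invitation ages 40–74), and the mean and median lead
#' time among screen-detected cases with a defined latent symptomatic age.
#' With no screen-detected cases the proportions are 0 and the lead-time
#' statistics `NA`.
#'
#' @param records a diagnosis-record data.frame (columns `mode`, `dx_age`,
#'   `lead_time`).
#' @return one-row data.frame: `pct_screen`, `pct_screen_4074`,
#'   `lead_mean`, `lead_median`.
#' @export
lead_time_summary <- function(records) {
  n <- nrow(records)
  scr <- records$mode == "screen"
  inv <- records$dx_age >= 40 & records$dx_age < 75
  lead <- records$lead_time[scr & !is.na(records$lead_time)]
  data.frame(
    pct_screen = if (n) 100 * mean(scr) else 0,
    pct_screen_4074 = if (any(inv)) 100 * mean(scr[inv]) else 0,
    lead_mean = if (length(lead)) mean(lead) else NA_real_,
    lead_median = if (length(lead)) stats::median(lead) else NA_real_)
}

#' Run the full simulation experiment
#'
#' Repeats [run_replicate()] `n_reps` times with per-replicate seeds derived
#' from `seed`, stacking the per-scenario estimates.
#'
#' @param config a configuration list as from [default_config()].
#' @param seed master integer seed.
#' @param n_reps number of replicates; defaults to the configured value.
#' @return data.frame of estimates with a `rep` column.
#' @export
run_experiment <- function(config, seed,
                           n_reps = config$experiment$n_reps) {
  objects <- config_objects(config)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    est <- run_replicate(config, seed = stage_seed(seed, 1000L + r),
                         objects = objects)
    out[[r]] <- cbind(rep = r, est)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative difference in percent
#'
#' `100 * (value - reference) / reference` — the relative (lead-time) bias
#' of an estimate against its no-screening reference.
#'
#' @param value,reference numeric.
#' @return percentage.
#' @examples
#' relative_difference(54.81, 50.96)  # 7.55...
#' @export
relative_difference <- function(value, reference) {
  100 * (value - reference) / reference
}

#' Lead-time bias summaries across replicates
#'
#' For each metric and screening scenario, summarises the per-replicate
#' differences against the reference (no-screening) scenario: the bias
#' (mean difference), its Monte Carlo standard error (SD of the differences
#' divided by the square root of the number of replicates), a 95% confidence
#' interval (bias ± 1.96 MCSE), the empirical 2.5 and 97.5 percentiles of
#' the differences, and the relative bias both as the mean of per-replicate
#' relative differences (`rel_bias`) and as the relative difference of the
#' means (`rel_bias_of_means`).
#'
#' @param estimates stacked per-replicate estimates from [run_experiment()]
#'   (needs columns `rep`, `scenario` and the metrics).
#' @param metrics metric columns to summarise.
#' @param reference scenario name used as reference.
#' @return a `bias_table` data.frame, one row per scenario and metric.
#' @export
compute_bias <- function(estimates, metrics = c("rs10", "lle", "pll"),
                         reference = "none") {
  if (!"rep" %in% names(estimates))
    estimates$rep <- estimates$seed
  if (length(unique(estimates$rep)) < 2)
    stop("need at least 2 replicates")
  ref <- estimates[estimates$scenario == reference, ]
  if (nrow(ref) == 0) stop("reference scenario not found")
  rows <- list()
  for (scn in unique(estimates$scenario)) {
    cur <- estimates[estimates$scenario == scn, ]
    m <- merge(cur[, c("rep", metrics)], ref[, c("rep", metrics)],
               by = "rep", suffixes = c("", ".ref"))
    if (nrow(m) != nrow(cur) || nrow(m) != nrow(ref))
      stop("mismatched replicate sets between scenario and reference")
    for (met in metrics) {
      d <- m[[met]] - m[[paste0(met, ".ref")]]
      ok <- !is.na(d)
      d <- d[ok]
      nr <- length(d)
      relb <- relative_difference(m[[met]][ok], m[[paste0(met, ".ref")]][ok])
      mcse <- if (nr > 1) stats::sd(d) / sqrt(nr) else 0
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scn, metric = met, n_reps = nr,
        bias = mean(d), mcse = mcse,
        ci_lo = mean(d) - 1.96 * mcse, ci_hi = mean(d) + 1.96 * mcse,
        p2.5 = unname(stats::quantile(d, 0.025)),
        p97.5 = unname(stats::quantile(d, 0.975)),
        rel_bias = mean(relb),
        rel_bias_of_means = relative_difference(
          mean(m[[met]][ok]), mean(m[[paste0(met, ".ref")]][ok])))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("bias_table", "data.frame")
  res
}
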