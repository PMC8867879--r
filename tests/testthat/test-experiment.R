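# A reduced configuration shared across tests: the full cohort structure
# (so every ICSS age group is populated in the diagnosis window) with fewer
# women per birth year.
small_config <- function(cohort_size = 400) {
  cfg <- default_config(fast = TRUE)
  cfg$natural_history$cohort_size <- as.integer(cohort_size)
  cfg$estimation$min_events <- 10
  cfg
}

test_that("replicates are deterministic given the seed", {
  cfg <- small_config()
  a <- run_replicate(cfg, seed = 9)
  b <- run_replicate(cfg, seed = 9)
  expect_identical(a, b)
  c <- run_replicate(cfg, seed = 10)
  expect_false(identical(a$n, c$n))
})

test_that("zero-sensitivity screening collapses to the no-screening scenario", {
  cfg <- small_config()
  cfg$screening$sensitivities <- list(zero = c(beta1 = -1e6, beta2 = 0))
  cfg$screening$attendances <- "perfect"
  out <- run_replicate(cfg, seed = 12, keep_records = TRUE)
  rn <- out$records$none
  rz <- out$records$zero_perfect
  expect_equal(rn$id, rz$id)
  expect_equal(rn$dx_age, rz$dx_age)
  expect_true(all(rz$mode == "symptomatic"))
  est <- out$estimates
  expect_equal(est$rs10[est$scenario == "zero_perfect"],
               est$rs10[est$scenario == "none"])
  expect_equal(est$lle[est$scenario == "zero_perfect"],
               est$lle[est$scenario == "none"])
})

test_that("death ages are identical across scenarios and lead times non-negative", {
  cfg <- small_config()
  out <- run_replicate(cfg, seed = 13, keep_records = TRUE)
  recs <- out$records
  base <- do.call(rbind, lapply(names(recs), function(s) {
    data.frame(scenario = s, id = recs[[s]]$id,
               death_age = recs[[s]]$death_age)
  }))
  # for every woman appearing in several scenarios, death age is bit-identical
  split_death <- split(base$death_age, base$id)
  expect_true(all(vapply(split_death,
                         function(v) all(v == v[1]), TRUE)))
  for (r in recs) {
    expect_true(all(r$lead_time >= 0, na.rm = TRUE))
    expect_true(all(r$dx_age <= r$death_age))
    expect_true(all(r$fu >= 0 & r$fu <= 12))
  }
  # cohort-membership differences arise only through diagnosis-date shifts:
  # women in the no-screening window cohort missing from a screening cohort
  # must have been screen-diagnosable outside the window
  ids_none <- recs$none$id
  ids_scr <- recs$high_perfect$id
  moved <- setdiff(ids_none, ids_scr)
  pop <- out$population$women
  expect_true(all(pop$sympt_age[match(moved, pop$id)] > 0))  # all have latent
  full <- impose_screening(
    pop, screening_programme(sensitivity_scenarios()$high[1],
                             sensitivity_scenarios()$high[2]),
    attend = matrix(TRUE, nrow(pop), 18),
    detect_u = out$population$screening_u$detect)
  expect_true(all(moved %in% full$id))
})

test_that("scenario estimates carry plausible descriptives", {
  cfg <- small_config()
  est <- run_replicate(cfg, seed = 14)
  expect_equal(nrow(est), 7)
  none <- est[est$scenario == "none", ]
  scr <- est[est$scenario == "high_perfect", ]
  expect_equal(none$pct_screen, 0)
  expect_gt(scr$pct_screen, 0)
  expect_gte(scr$n, none$n)               # screening cohort at least as large
  expect_lte(scr$mean_age, none$mean_age) # and younger
  expect_gte(scr$pct_size_lt17.5, none$pct_size_lt17.5)  # smaller tumours
  shares <- est[, c("pct_size_lt17.5", "pct_size_17.5_32.5",
                    "pct_size_32.5_47.5", "pct_size_gt47.5")]
  expect_equal(unname(rowSums(shares)), rep(100, 7), tolerance = 1e-9)
})

test_that("cohort descriptives and lead-time summaries compute as documented", {
  one <- data.frame(id = 1L, mode = "symptomatic", dx_age = 60,
                    dx_year = 1972, diameter = 10, lead_time = 0,
                    death_age = 65, fu = 5, event = 1L)
  d <- summarize_cohort(one)
  expect_equal(d$n, 1L)
  expect_equal(d$mean_age, 60)
  expect_equal(d$median_age, 60)
  expect_equal(d$pct_dead, 100)
  expect_equal(d$pct_size_lt17.5, 100)
  # bins are left-closed at the printed cut points
  b <- summarize_cohort(transform(one, diameter = 17.5))
  expect_equal(b$pct_size_17.5_32.5, 100)

  s <- lead_time_summary(one)
  expect_equal(s$pct_screen, 0)
  expect_true(is.na(s$lead_mean))
  three <- data.frame(mode = rep("screen", 3), dx_age = c(50, 60, 70),
                      lead_time = c(1, 2, 6))
  s3 <- lead_time_summary(three)
  expect_equal(s3$pct_screen, 100)
  expect_equal(s3$lead_mean, 3)
  expect_equal(s3$lead_median, 2)
})

test_that("bias tables aggregate replicate differences correctly", {
  # hand-built estimates: two replicates, reference plus one scenario
  est <- data.frame(
    rep = c(1, 2, 1, 2),
    scenario = c("none", "none", "s", "s"),
    rs10 = c(10, 20, 11, 23),
    lle = c(5, 5, 5, 5),
    pll = c(0.5, 0.4, 0.5, 0.4))
  bt <- compute_bias(est)
  row <- bt[bt$scenario == "s" & bt$metric == "rs10", ]
  expect_equal(row$bias, 2)          # mean of (+1, +3)
  expect_equal(row$mcse, 1)          # sd = sqrt(2), / sqrt(2)
  expect_equal(row$ci_lo, 2 - 1.96)
  expect_equal(row$ci_hi, 2 + 1.96)
  # identical scenario: zero bias and zero MCSE for every metric
  self <- bt[bt$scenario == "none", ]
  expect_true(all(self$bias == 0 & self$mcse == 0))
  # antisymmetry: swapping scenario and reference negates the bias
  bt_rev <- compute_bias(est, reference = "s")
  expect_equal(bt_rev$bias[bt_rev$scenario == "none" &
                             bt_rev$metric == "rs10"], -row$bias)
  expect_error(compute_bias(est[est$rep == 1, ]), "at least 2")
})

test_that("the printed-value relative-difference arithmetic holds", {
  expect_equal(round(relative_difference(54.81, 50.96), 1), 7.6)
  expect_equal(relative_difference(50, 50), 0)
  expect_equal(relative_difference(45, 50), -10)
})

test_that("YAML configurations merge over the defaults", {
  skip_if_not_installed("yaml")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "natural_history:",
    "  cohort_size: 250",
    "  eta: 0.0005",
    "screening:",
    "  p_low: 0.2",
    "generating_fpm:",
    "  knots: [-2.0, 2.5]",
    "  gamma: [-2.5, 1.1]",
    "  alpha: 0.02",
    "  age_center: 60"), f)
  cfg <- read_config(f, fast = TRUE)
  expect_equal(cfg$natural_history$cohort_size, 250)
  expect_equal(cfg$natural_history$eta, 5e-4)
  expect_equal(cfg$screening$p_low, 0.2)
  expect_equal(cfg$screening$p_high, 0.9)        # inherited default
  expect_s3_class(cfg$generating_fpm, "generating_fpm")
  expect_equal(cfg$generating_fpm$gamma, c(-2.5, 1.1))
  expect_equal(cfg$experiment$n_reps, 20L)
})
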