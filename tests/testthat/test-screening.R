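test_that("logistic sensitivity reproduces the three scenario values at 12 mm", {
  sc <- sensitivity_scenarios()
  sens12 <- vapply(sc, function(b) screening_sensitivity(12, b[1], b[2]), 0)
  expect_equal(round(unname(sens12), 2), c(0.58, 0.84, 0.96))
  expect_equal(screening_sensitivity(0, 0, 0), 0.5)
  expect_equal(screening_sensitivity(c(1, 30), -2, 0), rep(plogis(-2), 2))
  # overflow-safe at extreme diameters
  expect_equal(screening_sensitivity(1e5, 0, 1), 1)
  expect_error(screening_sensitivity(-1, 0, 1), "non-negative")
})

test_that("attendance model mixes high and low attenders as specified", {
  prog <- screening_programme(-5, 0.5, attendance = "perfect")
  expect_equal(length(prog$visits), 18)
  expect_true(all(simulate_attendance(prog, 25)))

  progi <- screening_programme(-5, 0.5, attendance = "imperfect")
  set.seed(51)
  att <- simulate_attendance(progi, 1e5)
  expect_lt(abs(mean(att) - (0.8 * 0.9 + 0.2 * 0.15)), 0.005)

  dead <- screening_programme(-5, 0.5, attendance = "imperfect",
                              p_high = 1e-12, p_low = 0)
  expect_true(!any(simulate_attendance(dead, 100)))
  expect_error(screening_programme(-5, 0.5, p_high = 0.1, p_low = 0.5),
               "p_low")
})

test_that("imposing screening follows the first-qualifying-visit rule", {
  hist1 <- data.frame(id = 1L, birth_year = 1915, onset_age = 38,
                      tau = 1e9, sympt_age = 45, death_age = 90)
  prog_on <- screening_programme(beta1 = 50, beta2 = 0)  # sensitivity ~ 1
  att <- matrix(TRUE, 1, 18)
  u <- matrix(0.5, 1, 18)
  r <- impose_screening(hist1, prog_on, attend = att, detect_u = u)
  expect_equal(r$mode, "screen")
  expect_equal(r$dx_age, 40)          # first visit after onset
  expect_equal(r$lead_time, 5)
  expect_equal(r$dx_year, 1955)

  # no attended visits: pure symptomatic diagnosis with zero lead time
  hist2 <- data.frame(id = 2L, birth_year = 1915, onset_age = 50,
                      tau = 0.7, sympt_age = 55, death_age = 80)
  r2 <- impose_screening(hist2, prog_on, attend = NULL)
  expect_equal(r2$mode, "symptomatic")
  expect_equal(r2$dx_age, 55)
  expect_equal(r2$lead_time, 0)

  # symptomatic age beyond death: included only via screening
  hist3 <- data.frame(id = 3L, birth_year = 1900, onset_age = 60,
                      tau = 1e9, sympt_age = 77, death_age = 70)
  r3on <- impose_screening(hist3, prog_on, attend = att, detect_u = u)
  expect_equal(r3on$mode, "screen")
  expect_true(r3on$latent_beyond_death)
  r3off <- impose_screening(hist3, prog_on, attend = NULL)
  expect_equal(nrow(r3off), 0)

  # visits at or after death never detect
  expect_true(all(r3on$dx_age < hist3$death_age))
})

test_that("administrative censoring at 12 years uses a strict boundary", {
  r <- make_record(c(60, 60, 60), c(65, 80, 72))
  expect_equal(r$fu, c(5, 12, 12))
  expect_equal(r$event, c(1L, 0L, 0L))  # death at exactly 12 is censored
  expect_error(make_record(60, 59), "negative")
})

test_that("lead times are non-negative and ordered across sensitivities", {
  lt <- make_synthetic_lifetable(a = 5e-5, b = 0.09, c = 1.5e-3,
                                 years = 1870:2066)
  op <- default_onset_probs()
  nh <- natural_history_params(op$age, op$prob, cohort_size = 400,
                               birth_years = 1900:1925)
  pop <- simulate_latent_population(nh, lt, default_generating_fpm(),
                                    seed = 5)
  att <- matrix(TRUE, nrow(pop$women), 18)
  out <- lapply(sensitivity_scenarios(), function(b) {
    prog <- screening_programme(b[1], b[2], attendance = "perfect")
    impose_screening(pop$women, prog, attend = att,
                     detect_u = pop$screening_u$detect)
  })
  for (r in out) expect_true(all(r$lead_time >= 0, na.rm = TRUE))
  mean_lead <- vapply(out, function(r)
    mean(r$lead_time[r$mode == "screen"], na.rm = TRUE), 0)
  pct_screen <- vapply(out, function(r) mean(r$mode == "screen"), 0)
  expect_true(all(diff(mean_lead) > 0))    # low < moderate < high
  expect_true(all(diff(pct_screen) > 0))

  # imperfect attendance detects fewer than perfect at equal sensitivity
  b <- sensitivity_scenarios()$moderate
  prog_i <- screening_programme(b[1], b[2], attendance = "imperfect")
  att_i <- attendance_from_uniforms(prog_i, pop$screening_u$type,
                                    pop$screening_u$attend)
  r_i <- impose_screening(pop$women, prog_i, attend = att_i,
                          detect_u = pop$screening_u$detect)
  expect_lt(mean(r_i$mode == "screen"), pct_screen[["moderate"]])

  # screening never shrinks the diagnosed cohort on identical latent data
  prog_m <- screening_programme(b[1], b[2], attendance = "perfect")
  r_none <- impose_screening(pop$women, prog_m, attend = NULL)
  r_scr <- impose_screening(pop$women, prog_m, attend = att,
                            detect_u = pop$screening_u$detect)
  expect_gte(nrow(r_scr), nrow(r_none))
  expect_true(all(r_none$id %in% pop$women$id))
})
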