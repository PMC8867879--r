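test_that("df-1 fit is a Weibull model: closed forms and survreg agree", {
  m <- weibull_gfpm(g0 = -3.0, g1 = 1.3, alpha = 0.03, age_center = 60)
  set.seed(71)
  d <- simulate_net_records(m, 5000)
  fit <- fit_relative_survival_fpm(d$time, d$event, d$age,
                                   df_baseline = 1, df_tvc = 0)
  g <- fit$coef$gamma

  # predictions equal the Weibull closed form of the fitted coefficients
  tt <- c(0.3, 1, 4, 10)
  closed <- exp(-exp(g[1] + g[2] * log(tt) +
                       fit$coef$alpha * (70 - fit$age_center)))
  expect_equal(predict_relative_survival(fit, 70, tt), closed,
               tolerance = 1e-8)
  expect_equal(predict_relative_survival(fit, 70, 0), 1)

  # recovery of the generating parameters within 3 standard errors
  se <- sqrt(diag(fit$vcov))
  # generating intercept translated to the fit's own age centring
  truth_g0 <- -3.0 + 0.03 * (fit$age_center - 60)
  expect_lt(abs(g[1] - truth_g0), 3 * se[1])
  expect_lt(abs(g[2] - 1.3), 3 * se[2])
  expect_lt(abs(fit$coef$alpha - 0.03), 3 * se[3])

  # independent oracle: survival::survreg's Weibull AFT reparameterisation
  sr <- survival::survreg(survival::Surv(time, event) ~ age, data = d,
                          dist = "weibull")
  expect_equal(g[2], 1 / sr$scale, tolerance = 1e-4)
  expect_equal(fit$coef$alpha, -coef(sr)[["age"]] / sr$scale,
               tolerance = 1e-4)
  expect_equal(fit$loglik, sr$loglik[2], tolerance = 1e-6)
})

test_that("maximum likelihood matches a brute-force oracle on a tiny fixture", {
  m <- weibull_gfpm(g0 = -2.2, g1 = 1.1, alpha = 0, age_center = 0)
  set.seed(72)
  d <- simulate_net_records(m, 20, age_range = c(50, 70))
  hstar <- rep(0.01, 20)
  fit <- fit_relative_survival_fpm(d$time, d$event, d$age,
                                   expected_rate = hstar,
                                   df_baseline = 1, df_tvc = 0)
  # independently coded likelihood, maximised by Nelder-Mead multistart
  t <- pmax(d$time, 1 / 365.25)
  a <- d$age - mean(d$age)
  ll <- function(p) {
    Lam <- exp(p[1] + p[2] * log(t) + p[3] * a)
    lam <- Lam * p[2] / t
    if (any(lam <= 0)) return(1e10)
    -(sum(d$event * log(hstar + lam)) - sum(Lam))
  }
  best <- Inf
  for (s in list(c(-1, 1, 0), c(-2, 0.8, 0.01), c(-0.5, 1.5, -0.01))) {
    o <- optim(s, ll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_equal(fit$loglik, -best, tolerance = 1e-4)
})

test_that("df-3 relative-survival fit agrees with flexsurvspline", {
  skip_if_not_installed("flexsurv")
  m <- default_generating_fpm()
  set.seed(73)
  d <- simulate_net_records(m, 1500, age_range = c(40, 85))
  hstar <- rep(0.015, nrow(d))
  fit <- fit_relative_survival_fpm(d$time, d$event, d$age,
                                   expected_rate = hstar,
                                   df_baseline = 3, df_tvc = 0)
  fs <- flexsurv::flexsurvspline(
    survival::Surv(pmax(time, 1 / 365.25), event) ~ age, data = d,
    knots = fit$knots[2:3], bknots = fit$knots[c(1, 4)],
    bhazard = hstar, scale = "hazard")
  # flexsurv's likelihood includes no extra constants: same maximum
  expect_equal(fit$loglik, fs$loglik, tolerance = 1e-3)
  # and near-identical survival predictions across the follow-up range
  tt <- c(0.5, 2, 5, 10)
  mine <- predict_relative_survival(fit, 65, tt)
  theirs <- summary(fs, newdata = data.frame(age = 65), t = tt,
                    type = "survival", ci = FALSE, tidy = TRUE)$est
  expect_equal(mine, theirs, tolerance = 5e-3)
})

test_that("higher expected rates push the fitted excess hazard down", {
  m <- default_generating_fpm()
  set.seed(74)
  d <- simulate_net_records(m, 5000, age_range = c(45, 80))
  h1 <- rep(0.02, nrow(d))
  f1 <- fit_relative_survival_fpm(d$time, d$event, d$age, expected_rate = h1,
                                  df_baseline = 3, df_tvc = 0)
  f2 <- fit_relative_survival_fpm(d$time, d$event, d$age,
                                  expected_rate = 2 * h1,
                                  df_baseline = 3, df_tvc = 0,
                                  knots = f1$knots)
  # same all-cause data, larger expected component -> smaller excess
  expect_gt(predict_relative_survival(f2, 62, 10),
            predict_relative_survival(f1, 62, 10))
})

test_that("time-dependent age effects are estimable and R(t) is well behaved", {
  m <- default_generating_fpm()
  set.seed(75)
  d <- simulate_net_records(m, 2000, age_range = c(40, 85))
  fit <- fit_relative_survival_fpm(d$time, d$event, d$age,
                                   df_baseline = 3, df_tvc = 3)
  expect_equal(fit$convergence, 0)
  expect_equal(length(fit$coef$delta), 3)
  tt <- seq(0.05, 12, by = 0.05)
  for (age in c(45, 62, 80)) {
    R <- predict_relative_survival(fit, age, tt)
    expect_true(all(R > 0 & R <= 1))
    expect_true(all(diff(R) <= 1e-8))  # non-increasing on the fitted range
  }
})

test_that("fitted models round-trip through the plain-text parameter file", {
  m <- weibull_gfpm()
  set.seed(76)
  d <- simulate_net_records(m, 400)
  fit <- fit_relative_survival_fpm(d$time, d$event, d$age,
                                   df_baseline = 3, df_tvc = 3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_fpm_pars(fit, f)
  back <- read_fpm_pars(f)
  tt <- c(0.2, 1, 6, 11)
  expect_equal(predict_relative_survival(back, 57, tt),
               predict_relative_survival(fit, 57, tt), tolerance = 1e-12)
  expect_equal(back$loglik, fit$loglik)
})
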