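# Shared fixtures built in code.

# Life table with the same constant rate in every cell (cap row absorbing).
constant_lifetable <- function(rate, years = 1900:2100, age_cap = 100) {
  rates <- matrix(rate, age_cap + 1, length(years))
  rates[age_cap + 1, ] <- Inf
  lifetable(rates, 0:age_cap, years)
}

# Weibull-type (df-1) generating model: log Lambda = g0 + g1 log t + a*age.
weibull_gfpm <- function(g0 = -3.5, g1 = 1.2, alpha = 0.02, age_center = 60) {
  generating_fpm(knots = c(log(0.01), log(15)), gamma = c(g0, g1),
                 alpha = alpha, age_center = age_center)
}

# Records drawn from a generating model with zero expected rates and
# administrative censoring, for parameter-recovery tests.
simulate_net_records <- function(model, n, censor = 12,
                                 age_range = c(35, 90)) {
  age <- runif(n, age_range[1], age_range[2])
  tt <- simulate_cancer_death_time(model, age_dx = age,
                                   horizon = rep(200, n))
  tt[is.na(tt)] <- Inf
  data.frame(age = age,
             time = pmin(tt, censor),
             event = as.integer(tt < censor))
}
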