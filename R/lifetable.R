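#' Construct a life table of expected mortality rates
#'
#' A `lifetable` holds the expected (general-population) mortality rates
#' \eqn{h^*(a, y)} of the cancer-free comparison population, tabulated on a
#' complete grid of integer attained ages and calendar years. It supplies the
#' expected hazard of the relative-survival decomposition
#' \eqn{h(t) = h^*(t) + \lambda(t)}, the expected survival \eqn{S^*} used in
#' loss-in-life-expectancy integrals, and the rates for simulating other-cause
#' death. Rates are per person-year; the rate in the cell `(age, year)` applies
#' on the attained-age interval `[age, age + 1)` during calendar year
#' `[year, year + 1)`.
#'
#' The oldest tabulated age (`age_cap`, at least 100) is an absorbing open age
#' group: its rate is `Inf`, encoding certain death by the age cap.
#'
#' @param rates numeric matrix, `length(ages)` rows by `length(years)` columns.
#'   All entries must be positive; `Inf` is permitted only in the final
#'   (open age group) row.
#' @param ages integer vector of contiguous ages starting at 0.
#' @param years integer vector of contiguous calendar years.
#' @return An object of class `lifetable` with fields `rates`, `ages`, `years`
#'   and `age_cap = max(ages)`.
#' @seealso [make_synthetic_lifetable()], [read_lifetable()],
#'   [expected_survival()]
#' @export
lifetable <- function(rates, ages, years) {
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (length(ages) < 2L || any(diff(ages) != 1L) || ages[1] != 0L)
    stop("'ages' must be contiguous integers starting at 0")
  if (length(years) < 1L || any(diff(years) != 1L))
    stop("'years' must be contiguous integers")
  rates <- as.matrix(rates)
  if (nrow(rates) != length(ages) || ncol(rates) != length(years))
    stop("'rates' must be length(ages) x length(years)")
  if (anyNA(rates)) stop("missing rates in life table")
  if (any(rates <= 0)) stop("non-positive rates in life table")
  if (any(is.infinite(rates[-nrow(rates), ]), na.rm = TRUE))
    stop("infinite rates only allowed in the open age group (last row)")
  structure(
    list(rates = rates, ages = ages, years = years, age_cap = max(ages),
         sex = "female"),
    class = "lifetable"
  )
}

#' @export
print.lifetable <- function(x, ...) {
  cat("Life table (", x$sex, ")\n", sep = "")
  cat("  ages : 0 -", x$age_cap, "\n")
  cat("  years:", min(x$years), "-", max(x$years), "\n")
  fin <- x$rates[is.finite(x$rates)]
  cat("  rates: ", format(min(fin), digits = 3), " - ",
      format(max(fin), digits = 3), " per person-year\n", sep = "")
  invisible(x)
}

#' Generate a synthetic life table
#'
#' Builds a Gompertz–Makeham style life table as a stand-in for observed
#' national rates: `rate(age, year) = (c + a * exp(b * age)) *
#' drift^(year - reference_year)`, clamped below at `floor`. A per-year
#' multiplicative `drift < 1` gives a secular mortality improvement. The top
#' age (`age_cap`) is the absorbing open age group (rate `Inf`).
#'
#' @param a,b Gompertz level and log-slope per year of age; both `> 0`.
#' @param c Makeham (age-constant) component, `>= 0`.
#' @param drift per-year multiplicative change in rates (1 = no trend).
#' @param years integer vector of calendar years to tabulate.
#' @param age_cap oldest age (absorbing); at least 100.
#' @param reference_year year at which the drift factor equals 1.
#' @param floor lower clamp for rates, `> 0`.
#' @return A [lifetable()].
#' @examples
#' lt <- make_synthetic_lifetable(a = 1e-4, b = 0.1, c = 1e-3, years = 1950:2050)
#' lifetable_rate(lt, 0, 1950)  # c + a
#' @export
make_synthetic_lifetable <- function(a, b, c = 0, drift = 1,
                                     years,
                                     age_cap = 100,
                                     reference_year = min(years),
                                     floor = 1e-6) {
  if (length(years) == 0) stop("empty year range")
  if (!is.numeric(a) || a <= 0) stop("'a' must be positive")
  if (!is.numeric(b) || b <= 0) stop("'b' must be positive")
  if (c < 0) stop("'c' must be non-negative")
  if (drift <= 0) stop("'drift' must be positive")
  if (floor <= 0) stop("'floor' must be positive")
  if (age_cap < 100) stop("'age_cap' must be at least 100")
  years <- as.integer(years)
  ages <- 0:age_cap
  base <- c + a * exp(b * ages)
  rates <- outer(base, drift^(years - reference_year))
  rates <- pmax(rates, floor)
  rates[length(ages), ] <- Inf
  lifetable(rates, ages, years)
}

#' Read a life table from a text file
#'
#' Two dialects are supported: `"csv"`, a delimited file with (case
#' insensitive) columns `year`, `age` and `rate`; and `"hmd"`, the Human
#' Mortality Database period death-rate layout (`Mx_1x1` / `fltper`-style
#' whitespace tables with columns `Year`, `Age`, `Female`, `Male`, `Total`),
#' from which the `Female` column is taken. Open age groups written as e.g.
#' `"110+"` are mapped to their lower bound. The declared grid (all years
#' between the first and last year found, all ages between 0 and the maximum
#' found) must be complete: missing cells are an error, never silently
#' interpolated.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"hmd"`.
#' @return A [lifetable()].
#' @export
read_lifetable <- function(path, dialect = c("csv", "hmd")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- utils::read.csv(path, strip.white = TRUE)
    names(df) <- tolower(names(df))
    need <- c("year", "age", "rate")
    if (!all(need %in% names(df)))
      stop("csv life table needs columns year, age, rate")
    df <- df[, need]
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- grep("\\bYear\\b", lines)[1]
    if (is.na(hdr)) stop("cannot locate HMD header line (no 'Year' column)")
    df <- utils::read.table(text = lines[hdr:length(lines)], header = TRUE,
                            stringsAsFactors = FALSE)
    if (!all(c("Year", "Age", "Female") %in% names(df)))
      stop("HMD life table needs columns Year, Age, Female")
    df <- data.frame(year = df$Year, age = df$Age, rate = df$Female)
  }
  df$age <- sub("\\+$", "", as.character(df$age))
  df$age <- suppressWarnings(as.integer(df$age))
  df$year <- suppressWarnings(as.integer(df$year))
  df$rate <- suppressWarnings(as.numeric(as.character(df$rate)))
  if (anyNA(df$age) || anyNA(df$year) || anyNA(df$rate))
    stop("unparseable rows in life table file")
  if (any(df$rate <= 0)) stop("non-positive rates in life table file")
  years <- min(df$year):max(df$year)
  ages <- 0:max(df$age)
  if (anyDuplicated(df[, c("age", "year")]))
    stop("duplicate (age, year) cells in life table file")
  rates <- matrix(NA_real_, length(ages), length(years))
  rates[cbind(df$age + 1L, df$year - years[1] + 1L)] <- df$rate
  if (anyNA(rates)) {
    miss <- which(is.na(rates), arr.ind = TRUE)[1, ]
    stop(sprintf("life table grid incomplete: missing age %d, year %d",
                 ages[miss[1]], years[miss[2]]))
  }
  lifetable(rates, ages, years)
}

#' Look up expected mortality rates
#'
#' Vectorised lookup of \eqn{h^*} at integer attained age and calendar year.
#' Years outside the tabulated range are clamped to the nearest tabulated year
#' (the last year's rates are carried forward, matching the use of projected
#' rates beyond the observation period). Ages above the cap return `Inf`;
#' negative ages are an error.
#'
#' @param table a [lifetable()].
#' @param age,year numeric vectors (fractional values are floored).
#' @return numeric vector of rates per person-year.
#' @export
lifetable_rate <- function(table, age, year) {
  stopifnot(inherits(table, "lifetable"))
  age <- floor(age)
  year <- floor(year)
  if (any(age < 0)) stop("negative age")
  ai <- pmin(age, table$age_cap) + 1L
  yi <- pmin(pmax(year, table$years[1]), max(table$years)) - table$years[1] + 1L
  r <- table$rates[cbind(ai, yi)]
  r[age >= table$age_cap] <- Inf
  r
}

#' Cumulative expected hazard along an attained-age / calendar-time diagonal
#'
#' Integrates \eqn{h^*} from a (possibly fractional) starting age and calendar
#' year over follow-up `t`, treating the rate as a step function that changes
#' at every integer boundary of attained age *and* of calendar year (the
#' integral is split at each crossing of either grid line).
#'
#' @param table a [lifetable()].
#' @param age_at_start,year_at_start scalars, possibly fractional.
#' @param t numeric vector of follow-up times in years, all `>= 0` and with
#'   `age_at_start + t <= age_cap`.
#' @return numeric vector: \eqn{\int_0^t h^*(a_0 + u, y_0 + u)\,du}.
#' @export
expected_cumhaz <- function(table, age_at_start, year_at_start, t) {
  stopifnot(inherits(table, "lifetable"))
  if (any(t < 0)) stop("t must be non-negative")
  if (length(t) == 0) return(numeric(0))
  tmax <- max(t)
  if (age_at_start + tmax > table$age_cap + 1e-9)
    stop("horizon beyond the life table's age cap")
  if (tmax == 0) return(rep(0, length(t)))
  next_int <- function(x) floor(x) + 1 - x   # distance to next integer above
  cuts_a <- next_int(age_at_start) + 0:ceiling(tmax)
  cuts_y <- next_int(year_at_start) + 0:ceiling(tmax)
  brk <- sort(unique(c(0, tmax, cuts_a[cuts_a < tmax], cuts_y[cuts_y < tmax])))
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  rt <- lifetable_rate(table, age_at_start + mid, year_at_start + mid)
  H <- c(0, cumsum(rt * diff(brk)))
  # piecewise-linear interpolation of the cumulative hazard at the requested t
  idx <- findInterval(t, brk, rightmost.closed = TRUE)
  part <- ifelse(t > brk[idx], (t - brk[idx]) * rt[pmin(idx, length(rt))], 0)
  H[idx] + part
}

#' Expected survival of the cancer-free comparison population
#'
#' \eqn{S^*(t) = \exp(-\int_0^t h^*(a_0+u, y_0+u)\,du)} with the rate
#' piecewise constant on yearly attained-age and calendar intervals.
#' `S*(0) = 1` and the function is non-increasing in `t`.
#'
#' @inheritParams expected_cumhaz
#' @return numeric vector of survival probabilities.
#' @examples
#' lt <- make_synthetic_lifetable(a = 1e-5, b = 0.09, years = 1950:2100)
#' expected_survival(lt, age_at_start = 60, year_at_start = 1970, t = c(0, 5, 10))
#' @export
expected_survival <- function(table, age_at_start, year_at_start, t) {
  exp(-expected_cumhaz(table, age_at_start, year_at_start, t))
}
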