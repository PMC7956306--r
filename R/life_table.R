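#' Build a cohort life table
#'
#' Constructs a validated, closed cohort life table from an age-indexed
#' schedule of annual death probabilities \eqn{q_x}. The table is discrete
#' annual: each \eqn{q_x} is the probability that a life aged exactly `x`
#' dies before age `x + 1`.
#'
#' Abridged schedules are supported: gaps of up to `max_gap` years between
#' supplied ages (e.g. a 5-year grid) are filled by linear interpolation of
#' \eqn{\log q_x}. A schedule whose final supplied \eqn{q} is below 1 is
#' extended to `terminal_age` by log-linear extrapolation of \eqn{q}, capped
#' at 1; the final age always carries \eqn{q = 1} so the table closes.
#'
#' @param q Death probabilities. Either a named numeric vector (names are
#'   integer ages), a numeric vector accompanied by `ages`, or a data frame
#'   with columns `age` and `qx`.
#' @param ages Integer ages matching `q` when `q` is an unnamed vector.
#' @param sex `"male"` or `"female"`.
#' @param cohort Integer birth-cohort calendar year (metadata only; no
#'   mortality-improvement projection is applied).
#' @param state Health state of the lives the schedule describes:
#'   `"independent"` or `"dependent"`.
#' @param radix Survivors at the first age (default 100000). All derived
#'   quantities are radix-invariant.
#' @param terminal_age Maximum age \eqn{\omega} used to close a schedule that
#'   never reaches \eqn{q = 1} (default 120).
#' @param max_gap Largest run of missing ages that interpolation will fill
#'   (default 4, admitting 5-year grids).
#'
#' @return An object of class `life_table`: a list with integer `age`
#'   (from `age_start` to \eqn{\omega}), `qx`, survivors `lx` (length
#'   `length(age) + 1`, ending in 0 at \eqn{\omega + 1}), and the metadata
#'   fields `sex`, `cohort`, `state`, `radix`.
#'
#' @examples
#' lt <- life_table(c(`60` = 0.01, `61` = 0.012, `62` = 0.015),
#'                  sex = "male", cohort = 1970)
#' survival_prob(lt, 60, 2)
#' life_expectancy(lt, 60)
#' @export
life_table <- function(q, ages = NULL, sex = c("male", "female"),
                       cohort = NA_integer_,
                       state = c("independent", "dependent"),
                       radix = 1e5, terminal_age = 120L, max_gap = 4L) {
  sex <- match.arg(sex)
  state <- match.arg(state)
  if (is.data.frame(q)) {
    if (!all(c("age", "qx") %in% names(q)))
      stop("data-frame schedule needs columns 'age' and 'qx'")
    ages <- q$age
    q <- q$qx
  } else if (is.null(ages)) {
    if (is.null(names(q)))
      stop("supply ages via names(q), the 'ages' argument, or a data frame")
    ages <- as.numeric(names(q))
  }
  if (length(q) == 0L) stop("empty mortality schedule")
  if (anyNA(q) || anyNA(ages)) stop("NA in mortality schedule")
  if (any(ages != round(ages))) stop("ages must be integers")
  if (any(q < 0 | q > 1)) stop("death probabilities must lie in [0, 1]")
  if (!(radix > 0)) stop("radix must be positive")
  ord <- order(ages)
  ages <- as.integer(ages[ord])
  q <- as.numeric(q[ord])
  if (anyDuplicated(ages)) stop("duplicated ages in schedule")

  filled <- .fill_gaps(ages, q, max_gap)
  ages <- filled$age
  q <- filled$qx

  # the table closes at the first q = 1; the grid is kept, with q = 1
  # (and zero survivors) from there on
  hit <- which(q >= 1)
  if (length(hit)) {
    q[hit[1L]:length(q)] <- 1
  } else {
    ext <- .extend_schedule(ages, q, terminal_age)
    ages <- ext$age
    q <- ext$qx
  }

  lx <- radix * cumprod(c(1, 1 - q))  # length n + 1, lx[n + 1] = 0
  stopifnot(all(diff(lx) <= 0))

  structure(
    list(age = ages, qx = q, lx = lx, sex = sex,
         cohort = as.integer(cohort), state = state, radix = radix),
    class = "life_table"
  )
}

# linear interpolation of log q across gaps of <= max_gap missing years
.fill_gaps <- function(ages, q, max_gap) {
  gaps <- diff(ages) - 1L
  if (!length(gaps) || all(gaps == 0L))
    return(list(age = ages, qx = q))
  if (any(gaps > max_gap))
    stop("age gap of ", max(gaps), " years exceeds the interpolation limit (",
         max_gap, "); supply a denser schedule")
  full <- seq(ages[1L], ages[length(ages)])
  if (any(q == 0))
    stop("cannot log-interpolate across a zero death probability")
  qi <- exp(stats::approx(ages, log(q), xout = full)$y)
  list(age = full, qx = qi)
}

# log-linear extrapolation of q from the last two ages, capped at 1,
# then forced closure at terminal_age
.extend_schedule <- function(ages, q, terminal_age) {
  n <- length(q)
  last <- ages[n]
  if (last >= terminal_age) {
    q[n] <- 1
    return(list(age = ages, qx = q))
  }
  slope <- if (n >= 2L && q[n] > 0 && q[n - 1L] > 0) {
    (log(q[n]) - log(q[n - 1L])) / (ages[n] - ages[n - 1L])
  } else {
    0.1  # flat/degenerate schedule: a generic old-age doubling-ish rate
  }
  extra_ages <- seq(last + 1L, terminal_age)
  extra_q <- pmin(exp(log(max(q[n], 1e-12)) + slope * (extra_ages - last)), 1)
  q <- c(q, extra_q)
  q[length(q)] <- 1
  list(age = c(ages, extra_ages), qx = q)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> %s, %s, cohort %s\n", x$sex, x$state,
              ifelse(is.na(x$cohort), "?", x$cohort)))
  cat(sprintf("  ages %d-%d (omega), radix %g\n",
              x$age[1L], x$age[length(x$age)], x$radix))
  cat(sprintf("  e%d = %.1f (complete)\n", x$age[1L],
              life_expectancy(x, x$age[1L])))
  invisible(x)
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  data.frame(age = x$age, qx = x$qx, lx = x$lx[seq_along(x$age)])
}

.check_age <- function(table, x) {
  omega <- table$age[length(table$age)]
  if (x < table$age[1L] || x > omega)
    stop("age ", x, " outside table range [", table$age[1L], ", ", omega, "]")
  invisible(omega)
}

#' Survival probability over t years
#'
#' \eqn{{}_tp_x = \prod_{k=0}^{t-1}(1 - q_{x+k}) = l_{x+t} / l_x}: the
#' probability that a life aged `x` reaches age `x + t`.
#'
#' @param table A `life_table`.
#' @param x Integer attained age, within the table.
#' @param t Non-negative integer number of years; `x + t` may reach at most
#'   \eqn{\omega + 1} (where survival is exactly 0 by closure).
#' @return A probability in \[0, 1\].
#' @export
survival_prob <- function(table, x, t) {
  stopifnot(inherits(table, "life_table"), t >= 0, t == round(t))
  omega <- .check_age(table, x)
  if (x + t > omega + 1)
    stop("x + t = ", x + t, " beyond omega + 1 = ", omega + 1)
  i <- x - table$age[1L] + 1L
  if (table$lx[i] == 0) return(as.numeric(t == 0))  # extinct cohort
  table$lx[i + t] / table$lx[i]
}

#' Force of mortality at an age
#'
#' The constant intensity over \eqn{[x, x+1)} consistent with the annual
#' death probability: \eqn{\mu_x = -\log(1 - q_x)}.
#'
#' @inheritParams survival_prob
#' @return Instantaneous death rate per year.
#' @export
force_of_mortality <- function(table, x) {
  stopifnot(inherits(table, "life_table"))
  .check_age(table, x)
  qx <- table$qx[x - table$age[1L] + 1L]
  if (qx >= 1)
    stop("q = 1 at age ", x, ": the one-year force of mortality is infinite")
  -log(1 - qx)
}

#' Life expectancy at an age
#'
#' Curtate expectancy is the expected number of whole years survived,
#' \eqn{e_x = \sum_{t \ge 1} {}_tp_x}; complete expectancy adds the
#' conventional half-year for the fraction of the year of death,
#' \eqn{\mathring{e}_x = e_x + 1/2}. The default is complete.
#'
#' @inheritParams survival_prob
#' @param convention `"complete"` (default) or `"curtate"`.
#' @param terminal_age Optional truncation age `w`: the summation stops at
#'   survival to age `w - 1` (i.e. whole years lived before `w`), matching
#'   an annuity payable while alive and under age `w`. `NULL` (default) sums
#'   to the table's \eqn{\omega}.
#' @return Expectancy in years.
#' @export
life_expectancy <- function(table, x,
                            convention = c("complete", "curtate"),
                            terminal_age = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(table, "life_table"))
  omega <- .check_age(table, x)
  tmax <- if (is.null(terminal_age)) omega + 1L - x else {
    stopifnot(terminal_age > x)
    min(terminal_age - 1L, omega + 1L) - x
  }
  i <- x - table$age[1L] + 1L
  e <- if (tmax >= 1L && table$lx[i] > 0)
    sum(table$lx[i + seq_len(tmax)]) / table$lx[i] else 0
  if (convention == "complete") e + 0.5 else e
}
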