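#' Pension-to-LTC conversion factor at an age
#'
#' The conversion factor \eqn{\lambda^d_x = e_x / e^d_x} is the ratio of
#' independent to dependent life expectancy at age `x`. A pension `b` becomes
#' an LTC support benefit \eqn{b \lambda^d_x} on certified severe dependency:
#' the beneficiary is paid more per year over a shorter expected lifetime, so
#' the expected payout is unchanged.
#'
#' Conventions: `"complete"` and `"curtate"` use the corresponding life
#' expectancies; `"annuity_due"` uses the ratio of zero-interest annuity-due
#' values \eqn{(1 + e_x^{trunc}) / (1 + e^{d,trunc}_x)} with curtate
#' expectancies truncated at `terminal_age`, which makes the cost-free
#' equivalence [check_equivalence()] exact at zero interest.
#'
#' @param ind Independent-state `life_table`.
#' @param dep Dependent-state `life_table` for the same lives.
#' @param x Attained age covered by both tables.
#' @param convention `"complete"` (default), `"curtate"`, or `"annuity_due"`.
#' @param terminal_age Truncation age `w` for expectancy sums (required for
#'   `"annuity_due"`; optional otherwise).
#' @return The dimensionless factor \eqn{\lambda \ge 0}.
#' @export
conversion_factor <- function(ind, dep, x,
                              convention = c("complete", "curtate",
                                             "annuity_due"),
                              terminal_age = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(ind, "life_table"), inherits(dep, "life_table"))
  if (convention == "annuity_due") {
    if (is.null(terminal_age))
      stop("annuity_due convention needs a terminal_age")
    num <- 1 + life_expectancy(ind, x, "curtate", terminal_age)
    den <- 1 + life_expectancy(dep, x, "curtate", terminal_age)
  } else {
    num <- life_expectancy(ind, x, convention, terminal_age)
    den <- life_expectancy(dep, x, convention, terminal_age)
  }
  if (den == 0) stop("dependent expectancy is zero at age ", x,
                     ": conversion factor undefined")
  num / den
}

#' Converted LTC benefit
#'
#' @param b Annual benefit amount, >= 0.
#' @param lambda Conversion factor, >= 0.
#' @return `b * lambda`.
#' @export
converted_benefit <- function(b, lambda) {
  if (any(b < 0) || any(lambda < 0)) stop("b and lambda must be non-negative")
  b * lambda
}

#' Sex differential of dependent mortality
#'
#' The ratio-minus-one statistic \eqn{q^d_{female} / q^d_{male} - 1}
#' comparing female to male dependent mortality at an age. Positive values
#' mean dependent women die at a higher rate than dependent men.
#'
#' @param dep_f,dep_m Dependent-state tables (or data frames with columns
#'   `age` and `q`) for women and men.
#' @param x Attained age covered by both.
#' @return Dimensionless differential.
#' @export
sex_differential <- function(dep_f, dep_m, x) {
  qf <- .q_at(dep_f, x)
  qm <- .q_at(dep_m, x)
  if (qm == 0) stop("male dependent mortality is zero at age ", x)
  qf / qm - 1
}

.q_at <- function(obj, x) {
  if (inherits(obj, "life_table")) {
    .check_age(obj, x)
    return(obj$qx[x - obj$age[1L] + 1L])
  }
  if (is.data.frame(obj) && all(c("age", "q") %in% names(obj))) {
    i <- match(x, obj$age)
    if (is.na(i)) stop("age ", x, " not present")
    return(obj$q[i])
  }
  stop("expected a life_table or a data frame with columns age, q")
}

.e_at <- function(obj, x, convention, terminal_age = NULL) {
  if (inherits(obj, "life_table"))
    return(life_expectancy(obj, x, convention, terminal_age))
  i <- match(x, obj$age)
  if (is.na(i)) stop("age ", x, " not present")
  obj$e[i]
}

#' Build a per-age conversion schedule
#'
#' Computes, for every requested age, the conversion factor and the derived
#' comparison statistics: independent and dependent expectancy, the relative
#' excess mortality \eqn{q^d/q - 1} (and the literal difference
#' `abs_excess`), the expectancy gap \eqn{e - e^d} — equal to the expected
#' payment-years forgone under annual payments — and, when the other sex's
#' dependent table is supplied, the sex differential of dependent mortality.
#'
#' Two input modes share this schedule type: full-table mode, where `ind` and
#' `dep` are `life_table` objects and expectancies are computed from them;
#' and fixture mode, where they are data frames with columns `age`, `q`, `e`
#' carrying printed abridged values, used verbatim.
#'
#' @param ind,dep Independent and dependent inputs for one sex: `life_table`
#'   objects or `age`/`q`/`e` data frames.
#' @param ages Ages to tabulate (default: every age common to both inputs).
#' @param convention Expectancy convention for full-table mode (ignored in
#'   fixture mode, where printed expectancies are used as-is).
#' @param dep_other Optional dependent input for the opposite sex, used to
#'   fill the `sex_diff` column as (other / this − 1) when this sex is male,
#'   or (this / other − 1) when female — i.e. always female over male.
#' @param sex,cohort Metadata recorded on the schedule (taken from `ind`
#'   when it is a `life_table`).
#' @return A data frame of class `conversion_schedule` with columns `age`,
#'   `lambda`, `e_ind`, `e_dep`, `rel_excess`, `abs_excess`, `sex_diff`,
#'   `gap`.
#' @export
build_schedule <- function(ind, dep, ages = NULL,
                           convention = c("complete", "curtate"),
                           dep_other = NULL, sex = NULL, cohort = NULL) {
  convention <- match.arg(convention)
  fixture_mode <- !inherits(ind, "life_table")
  if (fixture_mode) {
    for (obj in list(ind, dep))
      if (!is.data.frame(obj) || !all(c("age", "q", "e") %in% names(obj)))
        stop("fixture-mode inputs need columns age, q, e")
  }
  if (is.null(ages)) ages <- intersect(ind$age, dep$age)
  if (!length(ages)) stop("no common ages")
  if (is.null(sex) && inherits(ind, "life_table")) sex <- ind$sex
  if (is.null(cohort) && inherits(ind, "life_table")) cohort <- ind$cohort

  rows <- lapply(ages, function(a) {
    qi <- .q_at(ind, a)
    qd <- .q_at(dep, a)
    ei <- .e_at(ind, a, convention)
    ed <- .e_at(dep, a, convention)
    rel <- if (qi == 0) NA_real_ else qd / qi - 1
    sd <- NA_real_
    if (!is.null(dep_other)) {
      qo <- .q_at(dep_other, a)
      sd <- if (identical(sex, "female")) {
        if (qo == 0) NA_real_ else qd / qo - 1
      } else {
        if (qd == 0) NA_real_ else qo / qd - 1
      }
    }
    data.frame(age = a, lambda = ei / ed, e_ind = ei, e_dep = ed,
               rel_excess = rel, abs_excess = qd - qi, sex_diff = sd,
               gap = ei - ed)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$rel_excess))
    warning("rel_excess undefined (q = 0) at age(s) ",
            paste(out$age[is.na(out$rel_excess)], collapse = ", "))
  structure(out,
            class = c("conversion_schedule", "data.frame"),
            sex = sex, cohort = cohort,
            convention = if (fixture_mode) "printed" else convention)
}

#' @export
print.conversion_schedule <- function(x, ...) {
  cat(sprintf("<conversion_schedule> %s, cohort %s, %s expectancies\n",
              attr(x, "sex") %||% "?", attr(x, "cohort") %||% "?",
              attr(x, "convention")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a conversion schedule
#'
#' Draws the conversion factor against age; the familiar shape on Spanish
#' data rises to a maximum in the mid-80s and then declines as dependent and
#' general mortality converge.
#'
#' @param x A `conversion_schedule`.
#' @param ... Passed to [plot()].
#' @export
plot.conversion_schedule <- function(x, ...) {
  plot(x$age, x$lambda, type = "b", pch = 16,
       xlab = "age", ylab = expression(lambda[x]^d),
       main = "Pension-to-LTC conversion factor", ...)
  invisible(x)
}
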