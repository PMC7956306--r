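#' Discount curve from instantaneous interest intensities
#'
#' A step function of the force of interest \eqn{\delta_t}: `rates[i]`
#' applies on `[times[i], times[i+1])`, the last rate extending to infinity.
#' The discount factor is \eqn{v(T) = \exp(-\int_0^T \delta_t\,dt)}, computed
#' exactly for the piecewise-constant intensity.
#'
#' @param rates Non-negative intensities per year (a single number gives a
#'   flat curve).
#' @param times Left endpoints of the steps, starting at 0.
#' @return An object of class `discount_curve`.
#' @export
discount_curve <- function(rates, times = 0) {
  if (length(rates) != length(times))
    stop("rates and times must have equal length")
  if (times[1L] != 0 || is.unsorted(times, strictly = TRUE))
    stop("times must start at 0 and be strictly increasing")
  structure(list(rates = rates, times = times), class = "discount_curve")
}

#' Discount factor to time T
#'
#' @param curve A [discount_curve()].
#' @param T Time in years, >= 0 (vectorised).
#' @return \eqn{v(T) = \exp(-\int_0^T \delta_t\,dt)}.
#' @export
discount_factor <- function(curve, T) {
  stopifnot(inherits(curve, "discount_curve"))
  if (any(T < 0)) stop("T must be non-negative")
  vapply(T, function(tt) {
    ends <- c(curve$times[-1L], Inf)
    widths <- pmin(tt, ends) - pmin(tt, curve$times)
    exp(-sum(curve$rates * widths))
  }, numeric(1))
}

#' Pension benefit specification
#'
#' @param benefit Annual benefit: a single amount, a numeric vector named by
#'   age, or a function of age.
#' @param retirement_age Age `r` at which payments can start.
#' @param terminal_age Age `w` bounding the payment stream (exclusive:
#'   payments cover whole years of life before `w`).
#' @return An object of class `pension_spec`.
#' @export
pension_spec <- function(benefit, retirement_age, terminal_age) {
  if (retirement_age >= terminal_age) stop("need retirement_age < terminal_age")
  if (is.numeric(benefit) && any(benefit < 0))
    stop("benefit must be non-negative")
  structure(list(benefit = benefit, retirement_age = retirement_age,
                 terminal_age = terminal_age), class = "pension_spec")
}

.benefit_at <- function(spec, age) {
  b <- spec$benefit
  if (is.function(b)) return(b(age))
  if (!is.null(names(b))) {
    v <- unname(b[as.character(age)])
    if (anyNA(v)) stop("benefit undefined at age(s) ",
                       paste(age[is.na(v)], collapse = ", "))
    return(v)
  }
  rep(b, length(age))
}

#' Present value of future benefits
#'
#' Actuarial present value at age `x` of the survival-contingent benefit
#' stream, discretised as an annual annuity-due: payments at the start of
#' each year of age survived to, from `x` up to (not including) the terminal
#' age `w`,
#' \deqn{PVFB_x = \sum_{t=0}^{w-x-1} b(x+t)\,{}_tp_x\,v(t).}
#' With unit benefit and zero interest this equals 1 plus the curtate life
#' expectancy truncated at `w`. An annuity-immediate timing (payments at
#' year ends) is available via `timing`.
#'
#' @param table A `life_table` covering `[x, w]`.
#' @param spec A [pension_spec()].
#' @param curve A [discount_curve()].
#' @param x Valuation age, in `[r, w)`.
#' @param timing `"due"` (default) or `"immediate"`.
#' @return Present value, in the benefit's currency units.
#' @export
pvfb <- function(table, spec, curve, x, timing = c("due", "immediate")) {
  timing <- match.arg(timing)
  stopifnot(inherits(table, "life_table"), inherits(spec, "pension_spec"),
            inherits(curve, "discount_curve"))
  if (x < spec$retirement_age || x >= spec$terminal_age)
    stop("valuation age must lie in [retirement_age, terminal_age)")
  omega <- table$age[length(table$age)]
  w <- min(spec$terminal_age, omega + 1L)
  ts <- if (timing == "due") 0:(w - x - 1L) else seq_len(w - x)
  if (!length(ts)) return(0)
  tp <- vapply(ts, function(t) survival_prob(table, x, t), numeric(1))
  sum(.benefit_at(spec, x + ts) * tp * discount_factor(curve, ts))
}

#' Cost-free equivalence residual
#'
#' Relative residual of the equivalence between the retirement annuity and
#' the converted LTC benefit:
#' \deqn{\frac{\lambda\,PVFB^{dep}_x - PVFB^{ind}_x}{PVFB^{ind}_x}.}
#' At zero interest, with \eqn{\lambda} from [conversion_factor()] under the
#' `"annuity_due"` convention truncated at the same terminal age, the
#' residual vanishes identically — the conversion transfers value without
#' new funding. At positive interest the life-expectancy-ratio \eqn{\lambda}
#' is an approximation and the signed residual quantifies it (the dependent
#' annuity is shorter, hence less discounted, so the residual is typically
#' positive).
#'
#' @param ind,dep Independent and dependent `life_table`s.
#' @param spec A [pension_spec()].
#' @param curve A [discount_curve()].
#' @param x Valuation age, >= retirement age.
#' @param lambda Conversion factor to test, > 0.
#' @param timing Annuity timing, as in [pvfb()].
#' @return Signed dimensionless residual.
#' @export
check_equivalence <- function(ind, dep, spec, curve, x, lambda,
                              timing = c("due", "immediate")) {
  timing <- match.arg(timing)
  if (lambda <= 0) stop("lambda must be positive")
  v_ind <- pvfb(ind, spec, curve, x, timing)
  v_dep <- pvfb(dep, spec, curve, x, timing)
  if (v_ind == 0) stop("independent-table present value is zero")
  (lambda * v_dep - v_ind) / v_ind
}
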