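#' Build a multistate transition table
#'
#' One row per age of the discrete annual multistate model. During activity
#' (ages below retirement) an active worker either stays active, becomes
#' disabled, dies, or retires; a retiree stays retired, dies, or becomes
#' severely dependent; a dependent stays dependent or dies. Only one
#' transition can occur per year and there is no return to previous states,
#' so each row's probabilities must sum to exactly 1.
#'
#' @param age Integer age(s).
#' @param phase `"active"`, `"retired"` or `"dependent"` (recycled).
#' @param p_stay Probability of remaining in the phase.
#' @param q_death Probability of dying within the year.
#' @param q_disab Probability of disablement (active phase only).
#' @param q_retire Probability of retiring (active phase only).
#' @param q_dependent Probability of becoming severely dependent (retired
#'   phase only).
#' @return A data frame of class `transition_table` with one row per
#'   (age, phase); inapplicable exit columns are `NA`.
#' @export
transition_table <- function(age, phase, p_stay, q_death,
                             q_disab = NA_real_, q_retire = NA_real_,
                             q_dependent = NA_real_) {
  phase <- match.arg(phase, c("active", "retired", "dependent"),
                     several.ok = TRUE)
  out <- data.frame(age = as.integer(age), phase = phase, p_stay = p_stay,
                    q_death = q_death, q_disab = q_disab,
                    q_retire = q_retire, q_dependent = q_dependent)
  class(out) <- c("transition_table", "data.frame")
  out
}

#' Validate transition-row closure
#'
#' Checks each row of a transition table against the closure identities of
#' the model: the phase-appropriate probabilities must sum to 1. Validation
#' reports — it never throws — so that a table assembled from noisy inputs
#' can be inspected as a whole.
#'
#' @param rows A `transition_table` (or compatible data frame).
#' @param tolerance Maximum allowed `|sum - 1|` (default 1e-9).
#' @return A data frame with columns `age`, `phase`, `row_sum`, `deviation`,
#'   `pass`, plus an `all_pass` attribute.
#' @export
validate_rows <- function(rows, tolerance = 1e-9) {
  sums <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    probs <- switch(as.character(r$phase),
      active    = c(r$p_stay, r$q_disab, r$q_death, r$q_retire),
      retired   = c(r$p_stay, r$q_death, r$q_dependent),
      dependent = c(r$p_stay, r$q_death))
    sum(probs)
  }, numeric(1))
  dev <- abs(sums - 1)
  rep <- data.frame(age = rows$age, phase = rows$phase, row_sum = sums,
                    deviation = dev, pass = dev <= tolerance)
  attr(rep, "all_pass") <- all(rep$pass)
  rep
}

#' Conversion-decision indicator
#'
#' Per-age 0/1 indicator of whether a retiree who becomes eligible chooses to
#' convert the pension into LTC support. The choice is exogenous here; once
#' taken it cannot be reversed, so the indicator must be non-decreasing.
#'
#' @param ages Integer ages the indicator covers.
#' @param convert_from Age from which the indicator is 1 (`Inf` means never).
#' @return Named integer vector of 0/1 over `ages`.
#' @export
conversion_decision <- function(ages, convert_from = Inf) {
  ind <- as.integer(ages >= convert_from)
  names(ind) <- ages
  ind
}

#' Project cohort state occupancy
#'
#' Deterministic expected-count projection of a cohort through the annual
#' multistate model. States: active, retired, dependent, plus the absorbing
#' disabled and (cumulative) dead. The retired-to-dependent flow at each age
#' is gated by the conversion decision: where the indicator is 0 the retiree
#' keeps the retirement pension, so that probability mass remains in the
#' retired state. Total mass (live states plus cumulative decrements) is
#' conserved at every step.
#'
#' @param rows A `transition_table` covering, for each projected age, every
#'   phase that is occupied at that age.
#' @param initial Named numeric vector of starting counts over
#'   `c(active, retired, dependent)` (missing states count 0).
#' @param start_age Age of the cohort at the first row of the projection.
#' @param horizon Number of annual steps to project.
#' @param decision Optional 0/1 vector from [conversion_decision()], named by
#'   age; default: always 1 (convert when dependent).
#' @return A matrix of class `occupancy` with `horizon + 1` rows (ages) and
#'   columns `active`, `retired`, `dependent`, `disabled`, `dead`.
#' @export
project_cohort <- function(rows, initial, start_age, horizon,
                           decision = NULL) {
  states <- c("active", "retired", "dependent", "disabled", "dead")
  occ <- matrix(0, nrow = horizon + 1L, ncol = 5L,
                dimnames = list(start_age + 0:horizon, states))
  init <- setNames(numeric(3), c("active", "retired", "dependent"))
  init[names(initial)] <- initial
  if (any(init < 0)) stop("initial counts must be non-negative")
  occ[1L, 1:3] <- init

  get_row <- function(a, ph) {
    i <- which(rows$age == a & rows$phase == ph)
    if (!length(i)) stop("no ", ph, " transition row for age ", a)
    rows[i[1L], ]
  }
  dec_at <- function(a) {
    if (is.null(decision)) return(1)
    d <- decision[as.character(a)]
    if (is.na(d)) 1 else as.numeric(d)
  }

  for (k in seq_len(horizon)) {
    a <- start_age + k - 1L
    cur <- occ[k, ]
    nxt <- c(active = 0, retired = 0, dependent = 0,
             disabled = cur[["disabled"]], dead = cur[["dead"]])
    if (cur[["active"]] > 0) {
      r <- get_row(a, "active")
      nxt[["active"]] <- nxt[["active"]] + cur[["active"]] * r$p_stay
      nxt[["disabled"]] <- nxt[["disabled"]] + cur[["active"]] * r$q_disab
      nxt[["dead"]] <- nxt[["dead"]] + cur[["active"]] * r$q_death
      nxt[["retired"]] <- nxt[["retired"]] + cur[["active"]] * r$q_retire
    }
    if (cur[["retired"]] > 0) {
      r <- get_row(a, "retired")
      d <- dec_at(a)
      flow_dep <- cur[["retired"]] * r$q_dependent * d
      nxt[["retired"]] <- nxt[["retired"]] +
        cur[["retired"]] * (r$p_stay + r$q_dependent * (1 - d))
      nxt[["dependent"]] <- nxt[["dependent"]] + flow_dep
      nxt[["dead"]] <- nxt[["dead"]] + cur[["retired"]] * r$q_death
    }
    if (cur[["dependent"]] > 0) {
      r <- get_row(a, "dependent")
      nxt[["dependent"]] <- nxt[["dependent"]] + cur[["dependent"]] * r$p_stay
      nxt[["dead"]] <- nxt[["dead"]] + cur[["dependent"]] * r$q_death
    }
    occ[k + 1L, ] <- nxt
  }
  total0 <- sum(occ[1L, ])
  drift <- abs(rowSums(occ) - total0)
  if (any(drift > 1e-9 * max(total0, 1)))
    stop("mass conservation violated during projection (max drift ",
         format(max(drift)), ")")
  structure(occ, class = c("occupancy", class(occ)))
}

#' Simulate individual paths through the multistate model
#'
#' Seeded Monte-Carlo companion to [project_cohort()] for demonstration:
#' samples `n` independent lives and tabulates state occupancy. The
#' deterministic projection is the reference; this sampler illustrates
#' sampling noise around it.
#'
#' @inheritParams project_cohort
#' @param n Number of simulated lives.
#' @param seed Integer RNG seed.
#' @param start_state State every life starts in.
#' @return An occupancy matrix of counts, as in [project_cohort()].
#' @export
simulate_cohort <- function(rows, n, start_age, horizon, decision = NULL,
                            seed = 1L, start_state = "active") {
  set.seed(seed)
  states <- c("active", "retired", "dependent", "disabled", "dead")
  state <- rep(start_state, n)
  occ <- matrix(0L, nrow = horizon + 1L, ncol = 5L,
                dimnames = list(start_age + 0:horizon, states))
  occ[1L, ] <- tabulate(factor(state, levels = states), 5L)
  dec_at <- function(a) {
    if (is.null(decision)) return(1)
    d <- decision[as.character(a)]
    if (is.na(d)) 1 else as.numeric(d)
  }
  for (k in seq_len(horizon)) {
    a <- start_age + k - 1L
    snapshot <- state  # transitions are resolved from the start-of-year state
    for (ph in c("active", "retired", "dependent")) {
      idx <- which(snapshot == ph)
      if (!length(idx)) next
      i <- which(rows$age == a & rows$phase == ph)
      if (!length(i)) stop("no ", ph, " transition row for age ", a)
      r <- rows[i[1L], ]
      pr <- switch(ph,
        active = c(active = r$p_stay, disabled = r$q_disab,
                   dead = r$q_death, retired = r$q_retire),
        retired = {
          d <- dec_at(a)
          c(retired = r$p_stay + r$q_dependent * (1 - d),
            dependent = r$q_dependent * d, dead = r$q_death)
        },
        dependent = c(dependent = r$p_stay, dead = r$q_death))
      state[idx] <- sample(names(pr), length(idx), replace = TRUE, prob = pr)
    }
    occ[k + 1L, ] <- tabulate(factor(state, levels = states), 5L)
  }
  structure(occ, class = c("occupancy", class(occ)))
}
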