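#' Gompertz-Makeham mortality law parameters
#'
#' Hazard \eqn{\mu_x = A + B c^x}: a constant background rate plus an
#' exponentially ageing component. The implied annual death probability is
#' the exact integral of the hazard over one year of age,
#' \deqn{q_x = 1 - \exp\!\left(-A - B c^x (c - 1)/\log c\right).}
#' Used here as a smooth synthetic stand-in for an adult insured-lives
#' mortality schedule (no real population table is reproduced).
#'
#' @param A Constant hazard, >= 0.
#' @param B Baseline of the ageing component, > 0 (0 gives pure-exponential
#'   survival).
#' @param c Rate of ageing, > 1 (ignored when `B = 0`).
#' @return An object of class `gm_params`.
#' @export
gm_params <- function(A = 2e-4, B = 3e-5, c = 1.1) {
  if (A < 0) stop("A must be non-negative")
  if (B < 0) stop("B must be non-negative")
  if (B > 0 && c <= 1) stop("c must exceed 1")
  structure(list(A = A, B = B, c = c), class = "gm_params")
}

#' Annual death probabilities under a Gompertz-Makeham law
#'
#' @param params A [gm_params()] object.
#' @param ages Integer ages.
#' @return Vector of \eqn{q_x} in \[0, 1).
#' @export
gm_qx <- function(params, ages) {
  stopifnot(inherits(params, "gm_params"))
  H <- rep(params$A, length(ages))
  if (params$B > 0)
    H <- H + params$B * params$c^ages * (params$c - 1) / log(params$c)
  1 - exp(-H)
}

#' Synthetic base (independent-lives) life table
#'
#' @param params A [gm_params()] object.
#' @param ages Age range of the schedule (default 20 to 120).
#' @inheritParams life_table
#' @return An independent-state `life_table`. Parameter combinations driving
#'   \eqn{q_x} to 1 before age 60 are rejected as implausible for an adult
#'   schedule.
#' @export
make_base_table <- function(params, ages = 20:120, sex = "male",
                            cohort = NA_integer_, radix = 1e5) {
  q <- gm_qx(params, ages)
  early <- ages < 60 & q >= 1 - 1e-12
  if (any(early))
    stop("implausible parameters: q reaches 1 before age 60")
  life_table(q, ages = ages, sex = sex, cohort = cohort,
             state = "independent", radix = radix,
             terminal_age = max(ages))
}

#' Synthetic (independent, dependent) table pair
#'
#' The dependent table is exactly the mixed-correction image of the
#' independent one, which makes the pair a round-trip oracle for
#' [fit_excess_params()].
#'
#' @inheritParams make_base_table
#' @param excess An [excess_params()] object.
#' @return List with elements `independent` and `dependent`.
#' @export
make_dependent_pair <- function(params, excess, ages = 20:120,
                                sex = "male", cohort = NA_integer_) {
  ind <- make_base_table(params, ages = ages, sex = sex, cohort = cohort)
  list(independent = ind, dependent = derive_dependent_table(ind, excess))
}

#' Printed 1970-cohort fixture (Spanish severe/high dependency)
#'
#' The published abridged values for the 1970 birth cohort: general and
#' severely-dependent death probabilities and life expectancies, both sexes,
#' ages 20 to 100 on a 5-year grid. Shipped verbatim (6-decimal q, 1-decimal
#' e), with no smoothing: interpolation, if needed, happens downstream in
#' [life_table()]. The dependent q-columns embody undisclosed
#' generational-table adjustments, so they are carried as data, not
#' re-derived from the packaged presets.
#'
#' @return Data frame with columns `age`, `q_male`, `q_female`, `e_male`,
#'   `e_female`, `qd_male`, `qd_female`, `ed_male`, `ed_female`.
#' @export
fixture_table3 <- function() {
  path <- system.file("extdata", "table3_cohort1970.csv",
                      package = "ltcfactor", mustWork = TRUE)
  utils::read.csv(path)
}

#' One sex/state slice of the 1970-cohort fixture
#'
#' Convenience accessor returning the `age`/`q`/`e` frame that
#' [build_schedule()] consumes in fixture mode.
#'
#' @param sex `"male"` or `"female"`.
#' @param state `"independent"` or `"dependent"`.
#' @return Data frame with columns `age`, `q`, `e`.
#' @export
fixture_slice <- function(sex = c("male", "female"),
                          state = c("independent", "dependent")) {
  sex <- match.arg(sex)
  state <- match.arg(state)
  tab <- fixture_table3()
  pre <- if (state == "independent") "" else "d"
  suf <- if (sex == "male") "male" else "female"
  data.frame(age = tab$age,
             q = tab[[paste0("q", pre, "_", suf)]],
             e = tab[[paste0("e", pre, "_", suf)]])
}

#' Ingest a fixture slice as a full life table
#'
#' Builds a `life_table` from the 5-year-grid fixture q-column: gaps are
#' filled by log-linear interpolation and the schedule is closed at the
#' default terminal age. Printed expectancies are not used here; the
#' rebuilt table carries its own closure assumptions, so its expectancies
#' will not match the printed abridged ones exactly.
#'
#' @inheritParams fixture_slice
#' @return A `life_table` for cohort 1970.
#' @export
fixture_life_table <- function(sex = c("male", "female"),
                               state = c("independent", "dependent")) {
  sex <- match.arg(sex)
  state <- match.arg(state)
  sl <- fixture_slice(sex, state)
  life_table(sl$q, ages = sl$age, sex = sex, cohort = 1970L, state = state)
}

#' Noisy fitting observations from a known parameter set
#'
#' Generates (age, q_general, q_dependent) observations where the dependent
#' column is the mixed-correction image of a Gompertz-Makeham base plus
#' uniform noise of a given amplitude — the stochastic-recovery harness for
#' [fit_excess_params()].
#'
#' @param params A [gm_params()] object.
#' @param excess An [excess_params()] object (the truth to recover).
#' @param ages Observation ages.
#' @param noise Half-width of the uniform perturbation added to the
#'   dependent probabilities (0 gives noiseless data).
#' @param seed Integer RNG seed (default 20210225).
#' @return Data frame with columns `age`, `q_general`, `q_dependent`.
#' @export
make_fit_observations <- function(params, excess, ages = seq(30, 108, by = 2),
                                  noise = 0, seed = 20210225L) {
  q <- gm_qx(params, ages)
  qd <- apply_mixed(q, ages, excess)
  if (noise > 0) {
    set.seed(seed)
    qd <- pmin(pmax(qd + stats::runif(length(qd), -noise, noise), 0), 1)
  }
  data.frame(age = ages, q_general = q, q_dependent = qd)
}
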