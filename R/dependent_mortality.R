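#' Excess-mortality parameters for severely dependent lives (mixed correction)
#'
#' Parameter set for the mixed logistic-plus-multiplicative correction that
#' turns a general mortality schedule into a severely/highly dependent one:
#' below `switch_age` an additive logistic-in-age excess is applied,
#' \deqn{q^d_x = q_x + \delta / (1 + \gamma^{x_i - x}),}
#' and from `switch_age` on a multiplicative loading is added,
#' \deqn{q^d_x = q_x (1 + \beta) + \delta / (1 + \gamma^{x_i - x}),}
#' reflecting the narrowing of absolute differentials at extreme ages.
#' Results are clipped to \[0, 1\].
#'
#' @param delta Asymptotic maximum additive excess, in (0, 1).
#' @param gamma Slope factor of the logistic, > 0. With \eqn{\gamma > 1} the
#'   additive term increases with age and tends to `delta`.
#' @param x_i Inflection age (years) where the logistic equals `delta / 2`.
#' @param beta Multiplicative loading on general mortality applied from
#'   `switch_age`, >= 0.
#' @param switch_age Attained age at which the multiplicative branch
#'   activates (default 95).
#' @param exponent Orientation of the logistic exponent: `"printed"`
#'   (default) uses \eqn{\gamma^{x_i - x}}; `"mirrored"` uses
#'   \eqn{\gamma^{x - x_i}} and is provided for experimentation only.
#' @return An object of class `excess_params`.
#' @seealso [excess_preset()] for the fitted Spanish severe/high-dependency
#'   values, [apply_mixed()], [derive_dependent_table()], [fit_excess_params()].
#' @export
excess_params <- function(delta, gamma, x_i, beta = 0, switch_age = 95L,
                          exponent = c("printed", "mirrored")) {
  exponent <- match.arg(exponent)
  if (!(delta > 0 && delta < 1)) stop("delta must lie in (0, 1)")
  if (!(gamma > 0)) stop("gamma must be positive")
  if (beta < 0) stop("beta must be non-negative")
  structure(list(delta = delta, gamma = gamma, x_i = x_i, beta = beta,
                 switch_age = as.integer(switch_age), exponent = exponent),
            class = "excess_params")
}

#' @export
print.excess_params <- function(x, ...) {
  cat(sprintf(
    "<excess_params> delta=%.4g gamma=%.4g x_i=%.4g beta=%.4g (switch age %d, %s exponent)\n",
    x$delta, x$gamma, x$x_i, x$beta, x$switch_age, x$exponent))
  invisible(x)
}

#' Packaged excess-mortality presets
#'
#' Least-squares fitted mixed-correction parameters for severe and high
#' dependency in Spain, by sex.
#'
#' @param name `"spain_severe_men"` or `"spain_severe_women"`.
#' @return An [excess_params()] object.
#' @export
excess_preset <- function(name = c("spain_severe_men", "spain_severe_women")) {
  name <- match.arg(name)
  switch(name,
    spain_severe_men   = excess_params(0.245, 1.135, 62.50, 0.1142),
    spain_severe_women = excess_params(0.165, 1.09,  58.61, 0.0962))
}

#' Simple (single-branch) excess-mortality corrections
#'
#' The two classical alternatives to the mixed correction: a constant
#' multiplicative loading \eqn{q^d = \min(\theta q, 1)} with \eqn{\theta \ge 1},
#' or an additive age-indexed excess \eqn{q^d = q + \varepsilon(x)} clipped to
#' \[0, 1\].
#'
#' @param kind `"multiplicative"` or `"additive"`.
#' @param theta Multiplicative factor, >= 1 (multiplicative kind).
#' @param epsilon Additive excess: a single number, a function of age, or a
#'   named numeric vector indexed by age (additive kind).
#' @return An object of class `simple_correction`.
#' @export
simple_correction <- function(kind = c("multiplicative", "additive"),
                              theta = NULL, epsilon = NULL) {
  kind <- match.arg(kind)
  if (kind == "multiplicative") {
    if (is.null(theta) || theta < 1)
      stop("multiplicative correction needs theta >= 1 ",
           "(theta < 1 would rank dependent mortality below general mortality)")
  } else {
    if (is.null(epsilon)) stop("additive correction needs epsilon")
  }
  structure(list(kind = kind, theta = theta, epsilon = epsilon),
            class = "simple_correction")
}

#' Multiplicative excess-mortality correction
#'
#' @param q General death probability/ies in \[0, 1\].
#' @param theta Loading factor >= 1.
#' @return `pmin(theta * q, 1)`.
#' @export
apply_multiplicative <- function(q, theta) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (theta < 1) stop("theta must be >= 1")
  pmin(theta * q, 1)
}

#' Additive excess-mortality correction
#'
#' @param q General death probability/ies in \[0, 1\].
#' @param x Attained age(s), recycled against `q`.
#' @param epsilon A number, a function of age, or a named vector by age.
#' @return `q + epsilon(x)` clipped to \[0, 1\].
#' @export
apply_additive <- function(q, x, epsilon) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  eps <- if (is.function(epsilon)) epsilon(x)
         else if (!is.null(names(epsilon))) unname(epsilon[as.character(x)])
         else epsilon
  pmin(pmax(q + eps, 0), 1)
}

# logistic additive excess at age x under a parameter set
.logistic_excess <- function(x, params) {
  expo <- if (params$exponent == "printed") params$x_i - x else x - params$x_i
  params$delta / (1 + params$gamma^expo)
}

#' Mixed excess-mortality correction
#'
#' Evaluates the mixed correction at given ages (see [excess_params()] for
#' the model). Vectorised over `q` and `x`.
#'
#' @param q General death probability/ies in \[0, 1\].
#' @param x Attained age(s).
#' @param params An [excess_params()] object.
#' @return Dependent death probabilities, clipped to \[0, 1\].
#' @export
apply_mixed <- function(q, x, params) {
  stopifnot(inherits(params, "excess_params"))
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  add <- .logistic_excess(x, params)
  mult <- ifelse(x >= params$switch_age, 1 + params$beta, 1)
  pmin(pmax(q * mult + add, 0), 1)
}

#' Derive a dependent-lives life table from an independent one
#'
#' Applies an excess-mortality correction age by age to an independent-state
#' table and rebuilds a dependent-state table on the same grid. The mortality
#' ordering \eqn{q^d_x \ge q_x} is verified post-clip and any violation is an
#' error. Because the mixed correction is piecewise in age, the table need
#' not be continuous at the switch age; the jump introduced there (the
#' \eqn{\beta q} increment) is reported in the `switch_jump` attribute rather
#' than smoothed away.
#'
#' @param base An independent-state `life_table`.
#' @param correction An [excess_params()] or [simple_correction()] object.
#' @return A dependent-state `life_table` on the same age grid, with
#'   attribute `switch_jump` (mixed correction only).
#' @export
derive_dependent_table <- function(base, correction) {
  stopifnot(inherits(base, "life_table"))
  if (base$state != "independent")
    stop("base table must describe independent lives")
  x <- base$age
  q <- base$qx
  jump <- NULL
  if (inherits(correction, "excess_params")) {
    qd <- apply_mixed(q, x, correction)
    sw <- correction$switch_age
    if (sw >= x[1L] && sw <= x[length(x)]) {
      qsw <- q[match(sw, x)]
      # size of the discontinuity the multiplicative branch introduces
      jump <- min(qsw * correction$beta, 1 - qsw)
    }
  } else if (inherits(correction, "simple_correction")) {
    qd <- if (correction$kind == "multiplicative")
      apply_multiplicative(q, correction$theta)
    else
      apply_additive(q, x, correction$epsilon)
  } else stop("correction must be excess_params or simple_correction")
  bad <- which(qd < q)
  if (length(bad))
    stop("ordering violation: corrected q below general q at age(s) ",
         paste(x[bad], collapse = ", "))
  out <- life_table(qd, ages = x, sex = base$sex, cohort = base$cohort,
                    state = "dependent", radix = base$radix,
                    terminal_age = x[length(x)])
  attr(out, "switch_jump") <- jump
  out
}

#' Fit mixed-correction parameters by least squares
#'
#' Estimates \eqn{(\delta, \gamma, x_i, \beta)} from paired observations of
#' general and dependent death probabilities by minimising the residual sum
#' of squares of the mixed-correction prediction. The surface is multimodal
#' in \eqn{(\gamma, x_i)}, so a coarse multistart grid seeds bounded
#' quasi-Newton minimisation; the best start is polished with
#' Levenberg-Marquardt.
#'
#' @param observations Data frame with columns `age`, `q_general`,
#'   `q_dependent`; at least 6 rows, with ages on both sides of the
#'   candidate inflection.
#' @param switch_age Age at which the multiplicative branch activates
#'   (default 95).
#' @param exponent Logistic orientation, as in [excess_params()].
#' @return An [excess_params()] object with attributes `rss` (residual sum
#'   of squares) and `converged` (logical; `FALSE` flags a best-so-far
#'   result).
#' @export
fit_excess_params <- function(observations, switch_age = 95L,
                              exponent = c("printed", "mirrored")) {
  exponent <- match.arg(exponent)
  obs <- as.data.frame(observations)
  need <- c("age", "q_general", "q_dependent")
  if (!all(need %in% names(obs)))
    stop("observations need columns ", paste(need, collapse = ", "))
  if (nrow(obs) < 6L) stop("need at least 6 observations")

  predict_qd <- function(p) {
    pars <- list(delta = p[1L], gamma = p[2L], x_i = p[3L], beta = p[4L],
                 switch_age = switch_age, exponent = exponent)
    add <- .logistic_excess(obs$age, pars)
    mult <- ifelse(obs$age >= switch_age, 1 + p[4L], 1)
    pmin(pmax(obs$q_general * mult + add, 0), 1)
  }
  rss_fn <- function(p) sum((obs$q_dependent - predict_qd(p))^2)

  excess0 <- pmax(obs$q_dependent - obs$q_general, 0)
  delta0 <- min(max(max(excess0), 1e-4), 0.999)
  lower <- c(1e-6, 1e-3, min(obs$age) - 30, 0)
  upper <- c(1 - 1e-6, 10, max(obs$age) + 30, 5)

  starts <- expand.grid(
    delta = delta0,
    gamma = c(1.02, 1.05, 1.1, 1.2, 1.5),
    x_i = stats::quantile(obs$age, c(0.2, 0.4, 0.6, 0.8), names = FALSE),
    beta = c(0, 0.1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), rss_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")

  converged <- TRUE
  polished <- tryCatch({
    nf <- minpack.lm::nls.lm(
      par = best$par,
      fn = function(p) obs$q_dependent - predict_qd(p),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15))
    list(par = nf$par, value = sum(nf$fvec^2))
  }, error = function(e) NULL)
  if (!is.null(polished) && polished$value <= best$value) {
    best <- polished
  } else if (is.null(polished)) {
    converged <- FALSE
  }

  p <- best$par
  out <- excess_params(delta = min(max(p[1L], 1e-9), 1 - 1e-9),
                       gamma = p[2L], x_i = p[3L], beta = p[4L],
                       switch_age = switch_age, exponent = exponent)
  attr(out, "rss") <- best$value
  attr(out, "converged") <- converged
  out
}
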