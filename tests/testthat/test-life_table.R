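test_that("construction validates, closes and derives survivors correctly", {
  # hand product: constant q = 0.5 over ages 0-3 halves survivors each year
  lt <- life_table(rep(0.5, 4), ages = 0:3, radix = 8, terminal_age = 3)
  expect_equal(lt$lx, 8 * c(1, 1/2, 1/4, 1/8, 0))
  expect_equal(lt$qx[length(lt$qx)], 1)  # forced closure

  # single age with q = 1: l drops from radix to 0
  lt1 <- life_table(c(`100` = 1))
  expect_equal(lt1$age, 100L)
  expect_equal(lt1$lx, c(1e5, 0))

  # Table 3 men's independent column ingests as a valid cohort-1970 table
  lt3 <- fixture_life_table("male", "independent")
  expect_s3_class(lt3, "life_table")
  expect_identical(lt3$cohort, 1970L)
  expect_true(all(diff(lt3$lx) <= 0))
  expect_true(all(lt3$qx >= 0 & lt3$qx <= 1))

  expect_error(life_table(numeric(0), ages = integer(0)), "empty")
  expect_error(life_table(c(`20` = 1.2)), "\\[0, 1\\]")
  expect_error(life_table(c(`20` = 0.1, `30` = 0.2)), "gap")
})

test_that("survival probabilities follow the product rule and its edge cases", {
  lt <- flat_table(0.1, 50:60)
  expect_identical(survival_prob(lt, 50, 0), 1)        # empty product
  expect_equal(survival_prob(lt, 50, 2), 0.81)         # 0.9^2
  expect_equal(survival_prob(lt, 50, 11), 0)           # closure at omega
  expect_error(survival_prob(lt, 49, 1), "outside")
  expect_error(survival_prob(lt, 50, 12), "beyond")
})

test_that("survival semigroup: tpx * up(x+t) = (t+u)px on randomized tables", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    q <- runif(n, 0, 0.5)
    lt <- life_table(q, ages = seq(40, 40 + n - 1), terminal_age = 40 + n - 1)
    omega <- max(lt$age)
    t <- sample(0:(omega - 40), 1)
    u <- sample(0:(omega + 1 - 40 - t), 1)
    expect_equal(survival_prob(lt, 40, t) * survival_prob(lt, 40 + t, u),
                 survival_prob(lt, 40, t + u), tolerance = 1e-12)
  }
})

test_that("force of mortality is the constant-intensity bridge -log(1-q)", {
  lt <- life_table(c(0, 1 - exp(-1), 0.01, 1), ages = 60:63,
                   terminal_age = 63)
  expect_equal(force_of_mortality(lt, 60), 0)
  expect_equal(force_of_mortality(lt, 61), 1)
  expect_equal(force_of_mortality(lt, 62), -log(0.99))
  expect_equal(round(force_of_mortality(lt, 62), 8), 0.01005034)
  expect_error(force_of_mortality(lt, 63), "infinite")
})

test_that("life expectancy matches brute-force sums and conventions", {
  # q = (0.5, 0.5, 1): curtate e = 0.5 + 0.25 = 0.75
  lt <- toy3()
  expect_equal(life_expectancy(lt, 0, "curtate"), 0.75)
  expect_equal(life_expectancy(lt, 0, "complete"), 1.25)
  # at omega the curtate expectancy is 0 and complete adds the half year
  expect_equal(life_expectancy(lt, 2, "curtate"), 0)
  expect_equal(life_expectancy(lt, 2, "complete"), 0.5)
  # truncation at w sums whole years lived before w
  lt2 <- flat_table(0.1, 50:70)
  e_trunc <- sum(vapply(1:4, function(t) survival_prob(lt2, 50, t),
                        numeric(1)))
  expect_equal(life_expectancy(lt2, 50, "curtate", terminal_age = 55),
               e_trunc)
})

test_that("discrete expectancy agrees with continuous quadrature on a smooth law", {
  p <- gm_default()
  lt <- make_base_table(p, ages = 20:120)
  for (x in c(20, 40, 65, 80)) {
    # independent oracle: integrate exp(-integrated GM hazard) from age x
    surv <- function(t) exp(-p$A * t - p$B * p$c^x * (p$c^t - 1) / log(p$c))
    e_cont <- stats::integrate(surv, 0, 120 - x, rel.tol = 1e-10)$value
    expect_equal(life_expectancy(lt, x, "complete"), e_cont, tolerance = 0.6)
  }
})

test_that("expectancy decreases under uniform upward mortality shifts", {
  set.seed(7)
  for (rep in 1:10) {
    q <- runif(30, 0.01, 0.3)
    lt1 <- life_table(q, ages = 40:69, terminal_age = 69)
    lt2 <- life_table(pmin(q + 0.05, 1), ages = 40:69, terminal_age = 69)
    expect_lt(life_expectancy(lt2, 40), life_expectancy(lt1, 40))
  }
})

test_that("5-year-grid ingestion recovers a smooth schedule within 5% per age", {
  for (p in list(gm_default(), gm_params(A = 0, B = 3e-5, c = 1.1))) {
    q_true <- gm_qx(p, 20:100)
    grid <- seq(20, 100, by = 5)
    lt_abridged <- life_table(gm_qx(p, grid), ages = grid, sex = "male")
    q_rec <- lt_abridged$qx[match(20:100, lt_abridged$age)]
    expect_true(all(abs(q_rec / q_true - 1) < 0.05))
  }
})

test_that("derived quantities are radix-invariant and s + F = 1", {
  q <- c(0.1, 0.2, 0.3, 1)
  a <- life_table(q, ages = 70:73, radix = 1e5, terminal_age = 73)
  b <- life_table(q, ages = 70:73, radix = 1, terminal_age = 73)
  expect_equal(life_expectancy(a, 70), life_expectancy(b, 70))
  expect_equal(survival_prob(a, 70, 3), survival_prob(b, 70, 3))
  s <- a$lx / a$lx[1]
  expect_equal(s + (1 - s), rep(1, length(s)))
  expect_true(all(diff(s) <= 0))
})
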