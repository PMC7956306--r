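test_that("row validation reports closure deviations without throwing", {
  rows <- rbind(
    transition_table(40, "active", p_stay = 0.90, q_death = 0.02,
                     q_disab = 0.03, q_retire = 0.05),
    transition_table(70, "retired", p_stay = 0.95, q_death = 0.04,
                     q_dependent = 0.02),
    transition_table(80, "dependent", p_stay = 0.7, q_death = 0.3))
  rep <- validate_rows(rows)
  expect_false(attr(rep, "all_pass"))
  expect_true(rep$pass[1])
  expect_false(rep$pass[2])
  expect_equal(rep$deviation[2], 0.01)
  expect_true(rep$pass[3])
})

test_that("dependent rows (p, 1 - p) always close", {
  set.seed(3)
  p <- runif(1000)
  rows <- transition_table(rep(80L, 1000), "dependent", p_stay = p,
                           q_death = 1 - p)
  expect_true(attr(validate_rows(rows), "all_pass"))
})

test_that("projection matches a hand-multiplied chain and conserves mass", {
  rows <- rbind(
    transition_table(60:62, "active", p_stay = 0.8, q_death = 0.2,
                     q_disab = 0, q_retire = 0))
  occ <- project_cohort(rows, c(active = 1000), start_age = 60, horizon = 3)
  expect_equal(unname(occ[, "active"]), 1000 * c(1, 0.8, 0.64, 0.512))
  expect_equal(unname(occ[, "dead"]), 1000 - 1000 * c(1, 0.8, 0.64, 0.512))
  expect_equal(unname(rowSums(occ)), rep(1000, 4), tolerance = 1e-12)

  # certain death in one step
  r1 <- transition_table(60, "active", p_stay = 0, q_death = 1,
                         q_disab = 0, q_retire = 0)
  o1 <- project_cohort(r1, c(active = 500), 60, 1)
  expect_equal(unname(o1[2, "dead"]), 500)
  # no exits at all: occupancy is constant
  r0 <- transition_table(60:64, "retired", p_stay = 1, q_death = 0,
                         q_dependent = 0)
  o0 <- project_cohort(r0, c(retired = 100), 60, 5)
  expect_true(all(o0[, "retired"] == 100))
})

test_that("mass is conserved and death is monotone on random chains", {
  set.seed(99)
  for (rep in 1:10) {
    ages <- 65:90
    qd <- runif(length(ages), 0, 0.2)
    qdep <- runif(length(ages), 0, 0.1)
    rows <- transition_table(ages, "retired",
                             p_stay = 1 - qd - qdep, q_death = qd,
                             q_dependent = qdep)
    rows <- rbind(rows,
                  transition_table(ages, "dependent",
                                   p_stay = 1 - pmin(qd * 3, 1),
                                   q_death = pmin(qd * 3, 1)))
    occ <- project_cohort(rows, c(retired = 1e5), 65, length(ages))
    expect_true(all(abs(rowSums(occ) - 1e5) <= 1e-9 * 1e5))
    expect_true(all(diff(occ[, "dead"]) >= -1e-12))
  }
})

test_that("the conversion decision gates the dependent flow and keeps mass", {
  ages <- 65:75
  rows <- rbind(
    transition_table(ages, "retired", p_stay = 0.85, q_death = 0.05,
                     q_dependent = 0.10),
    transition_table(ages, "dependent", p_stay = 0.8, q_death = 0.2))
  never <- conversion_decision(ages, convert_from = Inf)
  from70 <- conversion_decision(ages, convert_from = 70)
  expect_true(all(diff(from70) >= 0))  # once 1, stays 1

  o_never <- project_cohort(rows, c(retired = 1000), 65, 10, never)
  expect_true(all(o_never[, "dependent"] == 0))
  o_70 <- project_cohort(rows, c(retired = 1000), 65, 10, from70)
  expect_true(all(o_70[as.integer(rownames(o_70)) <= 70, "dependent"] == 0))
  expect_gt(o_70[11, "dependent"], 0)
  expect_equal(unname(rowSums(o_70)), rep(1000, 11), tolerance = 1e-9)
})

test_that("dependent survivorship is dominated by independent survivorship", {
  base <- make_base_table(gm_default(), ages = 65:120)
  dep <- derive_dependent_table(base, men_preset())
  ages <- 65:119
  q_r <- base$qx[match(ages, base$age)]
  q_d <- dep$qx[match(ages, dep$age)]
  rows <- rbind(
    transition_table(ages, "retired", p_stay = 1 - q_r, q_death = q_r,
                     q_dependent = 0),
    transition_table(ages, "dependent", p_stay = 1 - q_d, q_death = q_d))
  o_ind <- project_cohort(rows, c(retired = 1e5), 65, 40)
  o_dep <- project_cohort(rows, c(dependent = 1e5), 65, 40)
  expect_true(all(o_dep[, "dependent"] <= o_ind[, "retired"] + 1e-9))
})

test_that("the Monte-Carlo sampler tracks the deterministic projection", {
  ages <- 65:85
  rows <- rbind(
    transition_table(ages, "retired", p_stay = 0.88, q_death = 0.04,
                     q_dependent = 0.08),
    transition_table(ages, "dependent", p_stay = 0.75, q_death = 0.25))
  n <- 20000
  det <- project_cohort(rows, c(retired = n), 65, 20)
  sim <- simulate_cohort(rows, n, 65, 20, seed = 123,
                         start_state = "retired")
  expect_equal(unname(rowSums(sim)), rep(n, 21))  # lives are conserved
  # expected counts within a few standard errors
  expect_equal(sim[11, "dead"] / n, det[11, "dead"] / n, tolerance = 0.02)
})
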