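test_that("long-acting cohorts follow the adjacent-CCR averaging rule", {
  m <- toy_ccr_method()
  expect_equal(unname(longacting_cohort(100, m)), c(90, 70, 50, 30, 10))
  expect_equal(names(longacting_cohort(100, m)), as.character(0:4))
  expect_equal(unname(longacting_cohort(0, m)), rep(0, 5))
  allon <- method_spec("allon", "long-acting", max_duration = 4,
                       ccr = rep(1, 5))
  expect_equal(unname(longacting_cohort(100, allon)), rep(100, 4))
  expect_error(longacting_cohort(10, pill_method()), "long-acting")
  expect_error(longacting_cohort(-1, m), "non-negative")
})

test_that("sterilisation cohorts apply survival recursively and retire at 49", {
  a <- flat_assumptions(annual_survival_rate = 0.998, median_age = 40)
  traj <- sterilisation_cohort(100, 2000, a, horizon = 2030)
  expect_equal(traj[["0"]], 99.8)
  expect_equal(traj[["1"]], 99.8 * 0.998)
  expect_equal(length(traj), 10)  # ages 40..49 inclusive
  # immortal cohort stays constant until age-49 removal
  a1 <- flat_assumptions(annual_survival_rate = 1, median_age = 48)
  traj1 <- sterilisation_cohort(100, 2000, a1, horizon = 2030)
  expect_equal(unname(traj1), c(100, 100))  # ages 48 and 49 only
  expect_length(traj1, 2)
})

test_that("sterilisation cohorts error when demography misses a needed year", {
  a <- flat_assumptions(years = 2000:2003, median_age = 40)
  expect_error(sterilisation_cohort(100, 2000, a, horizon = 2010), "2004")
})

test_that("short-term users divide commodities by units-per-year", {
  pill <- pill_method()
  expect_equal(shortterm_users(13, pill), 1)
  expect_equal(shortterm_users(0, pill), 0)
  expect_equal(shortterm_users(130, pill), 10)
  expect_error(shortterm_users(5, toy_ccr_method()), "short-term")
})

test_that("cohort matrix column sums match the double-loop oracle", {
  fx <- random_fixture(11)
  horizon <- fx$y_end
  mat <- build_cohort_matrix(fx$history, fx$assumptions, horizon = horizon)
  for (y in (fx$y_start - 3):horizon) {
    u <- users_in_year(mat, fx$history, y, fx$assumptions, exclude = "condom")
    o <- oracle_users_in_year(fx$history, fx$assumptions, y, "condom")
    expect_equal(u$lapm, o$lapm, tolerance = 1e-9)
    expect_equal(u$short_term, o$short_term, tolerance = 1e-9)
    expect_equal(u$total, o$total, tolerance = 1e-9)
    expect_equal(u$total, u$lapm + u$short_term, tolerance = 1e-9)
  }
})

test_that("two cohorts of the same method superpose in the column sum", {
  a <- flat_assumptions()
  h <- service_history(c(2000L, 2001L), c("toy_la", "toy_la"), c(100, 50))
  mat <- build_cohort_matrix(h, a, horizon = 2006)
  u2001 <- users_in_year(mat, h, 2001, a)$lapm
  expect_equal(u2001, 70 + 45)  # 100*.7 (offset 1) + 50*.9 (offset 0)
  u2003 <- users_in_year(mat, h, 2003, a)$lapm
  expect_equal(u2003, 30 + 25)
})

test_that("unknown methods in the history are rejected with the known list", {
  a <- flat_assumptions()
  h <- service_history(2000L, "norplant99", 10)
  expect_error(build_cohort_matrix(h, a), "norplant99")
  expect_error(build_cohort_matrix(h, a), "toy_la")
})

test_that("excluded methods contribute zero users", {
  a <- flat_assumptions()
  h <- service_history(2005L, "condom", 1200)
  mat <- build_cohort_matrix(h, a, horizon = 2006)
  u <- users_in_year(mat, h, 2005, a, exclude = "condom")
  expect_equal(u$total, 0)
  u_incl <- users_in_year(mat, h, 2005, a, exclude = character())
  expect_equal(u_incl$total, 10)
  # a year before any services is all zeros
  expect_equal(users_in_year(mat, h, 2000, a)$total, 0)
})

test_that("first-year users discount LAPMs but not short-term methods", {
  a <- flat_assumptions(annual_survival_rate = 0.998)
  fy <- first_year_users(c(toy_la = 100, sterilisation = 100, pill = 26),
                         2005, a)
  expect_equal(fy[["toy_la"]], 90)          # mean(1, 0.8)
  expect_equal(fy[["sterilisation"]], 99.8)
  expect_equal(fy[["pill"]], 2)
})

test_that("CYP totals multiply services by method factors", {
  a <- flat_assumptions(extra_methods = list(
    method_spec("iud10", "long-acting", max_duration = 10,
                ccr = c(1, .9, .8, .7, .6, .5, .4, .3, .2, .1, 0),
                cyp_factor = 4.6)))
  expect_equal(cyp_total(c(iud10 = 1), a), 4.6)
  expect_equal(cyp_total(c(pill = 15), a), 1)
  expect_equal(cyp_total(numeric(0), a), 0)
  a2 <- flat_assumptions(extra_methods = list(
    method_spec("nofactor", "short-term", units_per_year = 2)))
  expect_error(cyp_total(c(nofactor = 1), a2), "CYP factor")
})

test_that("user estimates are linear in services", {
  fx <- random_fixture(21)
  k <- 3.7
  scaled <- fx$history
  scaled$units <- scaled$units * k
  class(scaled) <- class(fx$history)
  years <- fx$y_start:fx$y_end
  u1 <- user_estimates(fx$history, fx$assumptions, years)
  u2 <- user_estimates(scaled, fx$assumptions, years)
  expect_equal(u2$total, k * u1$total, tolerance = 1e-9)
  expect_equal(u2$lapm, k * u1$lapm, tolerance = 1e-9)
})

test_that("cohort trajectories never increase and end at their removal year", {
  fx <- random_fixture(31)
  a <- fx$assumptions
  for (mn in names(a$methods)) {
    m <- a$methods[[mn]]
    if (m$category == "short-term") next
    traj <- if (m$category == "long-acting") longacting_cohort(500, m)
    else sterilisation_cohort(500, 2002, a)
    expect_true(all(diff(unname(traj)) <= 1e-9), info = mn)
    expect_true(all(traj >= 0), info = mn)
    if (m$category == "long-acting") {
      expect_length(traj, m$max_duration)  # absent from max_duration onward
    } else {
      expect_lte(max(as.integer(names(traj))),
                 floor(49 - a$median_age_sterilisation))
    }
  }
})
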