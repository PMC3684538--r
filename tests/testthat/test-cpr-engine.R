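test_that("baseline contribution divides users by the denominator", {
  a <- flat_assumptions(wra = 1e6)
  h <- service_history(2004L, "pill", 5000 * 13)
  b <- compute_baseline(h, a, 2004L)
  expect_equal(b$users, 5000)
  expect_equal(b$contribution, 0.005)  # 0.5% of WRA
  # empty history
  h0 <- service_history(integer(), character(), numeric())
  b0 <- compute_baseline(h0, a, 2004L)
  expect_equal(b0$users, 0)
  expect_equal(b0$contribution, 0)
})

test_that("pre-existing users are the old-cohort column sums", {
  a <- flat_assumptions()
  h <- service_history(2004L, "toy_la", 100)
  pre <- pre_existing_series(h, a, 2005:2008, y0 = 2004L)
  expect_equal(unname(pre), c(70, 50, 30, 10))  # tail of [90,70,...]
  # cohorts created inside the trend never count as pre-existing
  h2 <- service_history(2005L, "toy_la", 100)
  expect_equal(unname(pre_existing_series(h2, a, 2005:2008, 2004L)),
               rep(0, 4))
  # random fixture against the oracle restricted to old provision years
  fx <- random_fixture(41)
  yrs <- fx$y_start:fx$y_end
  pre_fx <- pre_existing_series(fx$history, fx$assumptions, yrs,
                                y0 = fx$y_start - 1L)
  for (i in seq_along(yrs)) {
    o <- oracle_users_in_year(fx$history, fx$assumptions, yrs[i], "condom",
                              max_provision_year = fx$y_start - 1L)
    expect_equal(unname(pre_fx[i]), o$lapm, tolerance = 1e-9)
  }
})

test_that("users needed to maintain is the clamped shortfall", {
  expect_equal(users_needed_to_maintain(1000, 400, 0), 600)
  expect_equal(users_needed_to_maintain(1000, 700, 400), 0)
  expect_equal(users_needed_to_maintain(0, 10, 10), 0)
})

test_that("new users are allocated across the three situations", {
  pr <- function(a, c_, p) list(adopters = a, continuers = c_, changers = p)
  # situation 3: continuers short, some adopters maintain
  al <- allocate_new_users(600, 1000, pr(0.30, 0.50, 0.20))
  expect_equal(al$situation, 3L)
  expect_equal(al$maintain, 600)
  expect_equal(al$increase, 200)
  # situation 1: continuers cover the gap, all adopters increase
  al <- allocate_new_users(600, 1000, pr(0.30, 0.65, 0.05))
  expect_equal(al$situation, 1L)
  expect_equal(al$maintain, 600)
  expect_equal(al$increase, 300)
  expect_equal(al$dropped_continuers, 50)
  # situation 2: everyone maintains, nothing increases
  al <- allocate_new_users(600, 500, pr(0.20, 0.40, 0.40))
  expect_equal(al$situation, 2L)
  expect_equal(al$maintain, 300)
  expect_equal(al$increase, 0)
  expect_error(allocate_new_users(1, 1, pr(0.5, 0.2, 0.2)), "profile")
})

test_that("counting fraction divides counted users by new users", {
  pr <- list(adopters = 0.30, continuers = 0.65, changers = 0.05)
  al <- allocate_new_users(600, 1000, pr)
  expect_equal(counting_fraction(al, 1000), 0.9)
  al2 <- allocate_new_users(600, 500,
                            list(adopters = 0.2, continuers = 0.4, changers = 0.4))
  expect_equal(counting_fraction(al2, 500), 0.6)
  expect_equal(counting_fraction(al2, 0), 0)
})

test_that("existing-user projection scales whole trajectories", {
  a <- flat_assumptions()
  yrs <- 2006:2010
  # fraction 0.5 on the [90, 70, 50, 30, 10] cohort: offsets 1-4 halved
  ex <- project_existing_users(c(toy_la = 100), 2005L, 0.5, a, yrs)
  expect_equal(unname(ex), c(35, 25, 15, 5, 0))
  # fraction 0 -> no existing users ever
  expect_equal(unname(project_existing_users(c(toy_la = 100), 2005L, 0, a, yrs)),
               rep(0, 5))
  # fraction 1 reproduces the cohort tail exactly
  ex1 <- project_existing_users(c(toy_la = 100), 2005L, 1, a, yrs)
  expect_equal(unname(ex1)[1:4], unname(longacting_cohort(100, a$methods$toy_la))[2:5])
})

test_that("an all-provider-changers profile contributes nothing", {
  fx <- random_fixture(51)
  prof <- client_profile(fx$y_start:fx$y_end, adopters = 0, continuers = 0,
                         changers = 1)
  tr <- run_trend(fx$history, fx$assumptions, prof, fx$y_start, fx$y_end)
  expect_equal(tr$years$counting_fraction, rep(0, nrow(tr$years)))
  expect_equal(tr$years$maintain + tr$years$increase,
               rep(0, nrow(tr$years)))
  expect_equal(tr$years$total_users_in_cpr,
               tr$years$pre_existing + tr$years$existing)
})

test_that("steady-state short-term services with constant WRA leave CPR flat", {
  a <- flat_assumptions(wra = 1e6)
  yrs <- 2000:2010
  h <- service_history(yrs, rep("pill", length(yrs)), rep(1300, length(yrs)))
  prof <- client_profile(2005:2010, adopters = 0, continuers = 1, changers = 0)
  tr <- run_trend(h, a, prof, 2005L, 2010L)
  expect_equal(tr$baseline$users, 100)
  expect_equal(tr$years$total_users_in_cpr, rep(100, 6))
  expect_equal(tr$years$pct_point_increase, rep(0, 6), tolerance = 1e-12)
})

test_that("constant users against a growing denominator lose ground", {
  yrs <- 1995:2030
  demo <- demographic_series(yrs, 1e6 * 1.03^(yrs - 1995),
                             rep(0.7, length(yrs)), rep(60, length(yrs)))
  a <- assumption_set(list(pill_method()), demo, flat_assumptions()$life_table)
  h <- service_history(2000:2010, rep("pill", 11), rep(1300, 11))
  prof <- client_profile(2005:2010, adopters = 0, continuers = 1, changers = 0)
  tr <- run_trend(h, a, prof, 2005L, 2010L)
  expect_true(all(diff(tr$years$pct_point_increase) < 0))
  expect_true(all(tr$years$pct_point_increase < 0))
})

test_that("the engine reproduces the straight-line oracle on random fixtures", {
  for (seed in c(61, 62, 63, 64, 65)) {
    fx <- random_fixture(seed)
    tr <- run_trend(fx$history, fx$assumptions, fx$profile,
                    fx$y_start, fx$y_end)
    o <- oracle_trend(fx$history, fx$assumptions, fx$profile,
                      fx$y_start, fx$y_end)
    expect_equal(tr$baseline$users, o$baseline_users, tolerance = 1e-9)
    for (col in c("pre_existing", "existing", "new_users", "situation",
                  "maintain", "increase", "counting_fraction",
                  "total_users_in_cpr", "total_pct_contribution",
                  "pct_point_increase"))
      expect_equal(tr$years[[col]], o$years[[col]], tolerance = 1e-9,
                   info = paste(seed, col))
  }
})

test_that("trend invariants hold on random fixtures", {
  for (seed in 71:75) {
    fx <- random_fixture(seed)
    tr <- run_trend(fx$history, fx$assumptions, fx$profile,
                    fx$y_start, fx$y_end)
    y <- tr$years
    # exact decomposition identity
    expect_identical(y$total_users_in_cpr,
                     y$pre_existing + y$existing + y$maintain + y$increase)
    # provider changers never counted
    pr <- tr$profile
    expect_true(all(y$counting_fraction <= pr$adopters + pr$continuers + 1e-9))
    expect_true(all(y$counting_fraction >= 0 & y$counting_fraction <= 1))
    # counted users never exceed modelled users
    um <- user_estimates(fx$history, fx$assumptions, y$year)
    expect_true(all(y$total_users_in_cpr <= um$total + 1e-9))
  }
})

test_that("zero-adopter profiles never create increase users", {
  for (seed in 81:83) {
    fx <- random_fixture(seed)
    prof <- client_profile(fx$y_start:fx$y_end, adopters = 0,
                           continuers = 0.6, changers = 0.4)
    tr <- run_trend(fx$history, fx$assumptions, prof, fx$y_start, fx$y_end)
    expect_equal(tr$years$increase, rep(0, nrow(tr$years)))
    expect_true(all(tr$years$pct_point_increase <= 1e-9))
  }
})

test_that("trend years with no services degrade gracefully", {
  a <- flat_assumptions()
  h <- service_history(2004L, "toy_la", 100)  # nothing during the trend
  prof <- client_profile(2005:2007, adopters = 0.3, continuers = 0.5,
                         changers = 0.2)
  tr <- run_trend(h, a, prof, 2005L, 2007L)
  expect_equal(tr$years$new_users, rep(0, 3))
  expect_equal(tr$years$counting_fraction, rep(0, 3))
  expect_equal(tr$years$total_users_in_cpr, c(70, 50, 30))
})

test_that("a profile gap inside the trend is an error", {
  fx <- random_fixture(91)
  prof <- client_profile(c(fx$y_start, fx$y_end), adopters = 0.3,
                         continuers = 0.5, changers = 0.2)
  expect_error(run_trend(fx$history, fx$assumptions, prof,
                         fx$y_start, fx$y_end), "missing year")
})
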