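# Small hand-rolled objects used across tests.

toy_ccr_method <- function(name = "toy_la") {
  method_spec(name, "long-acting", max_duration = 5,
              ccr = c(1, 0.8, 0.6, 0.4, 0.2, 0))
}

pill_method <- function() {
  method_spec("pill", "short-term", units_per_year = 13, cyp_factor = 1 / 15)
}

# A flat assumption set: constant WRA and e0, one constant-survival life
# table level so sterilisation survival is exactly `annual^5` per 5 years.
flat_assumptions <- function(years = 1995:2030, wra = 1e6,
                             annual_survival_rate = 0.998,
                             median_age = 40, cpr_basis = "all-women",
                             extra_methods = list()) {
  demo <- demographic_series(years, rep(wra, length(years)),
                             rep(0.7, length(years)), rep(60, length(years)))
  starts <- seq(15, 50, 5)
  lt <- life_table_family("flat", data.frame(
    e0_level = 60, age_group_start = starts,
    p5x = rep(annual_survival_rate^5, length(starts))))
  methods <- c(list(toy_ccr_method(), pill_method(),
                    method_spec("sterilisation", "permanent", cyp_factor = 10),
                    method_spec("condom", "short-term", units_per_year = 120,
                                cyp_factor = 1 / 120)),
               extra_methods)
  assumption_set(methods, demo, lt, median_age_sterilisation = median_age,
                 cpr_basis = cpr_basis)
}

# Seeded random fixture (history + assumptions + profile) for the
# property/oracle suites; always includes pre-baseline years.
random_fixture <- function(seed) {
  set.seed(seed)
  params <- fixture_params(
    n_years = sample(6:10, 1), start_year = sample(1996:2002, 1),
    base_services = stats::runif(1, 500, 30000),
    growth = stats::runif(1, -0.1, 0.4),
    noise_sd = stats::runif(1, 0, 0.3),
    wra0 = stats::runif(1, 5e5, 5e6),
    wra_growth = stats::runif(1, 0, 0.04),
    e0_range = sort(stats::runif(2, 52, 72)),
    median_age_sterilisation = stats::runif(1, 25, 42),
    seed = seed + 1000L)
  a <- stats::runif(1, 0, 0.6); p <- stats::runif(1, 0, 1 - a)
  history <- generate_service_history(params)
  assumptions <- generate_assumption_set(
    params, cpr_basis = sample(c("all-women", "in-union"), 1))
  y_start <- params$start_year + 4L
  y_end <- params$start_year + params$n_years - 1L
  profile <- client_profile(y_start:y_end, adopters = a,
                            continuers = 1 - a - p, changers = p)
  list(history = history, assumptions = assumptions, profile = profile,
       y_start = y_start, y_end = y_end)
}
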