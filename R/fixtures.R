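#' Parameters for the synthetic-data generator
#'
#' Controls for generating internally consistent synthetic service
#' histories and assumption sets. Defaults sketch a mid-sized
#' sub-Saharan programme: a mixed method portfolio growing ~20% a year, a
#' WRA population of five million growing 2.5% a year, life expectancy
#' rising through the period, and a client profile with roughly half
#' continuers. None of this claims statistical realism for any one
#' country; it reproduces the *structure* real inputs have (years x
#' methods units table, monotone CCRs, growing denominators).
#'
#' @param n_years Number of history years to generate.
#' @param start_year First history year (>= 1982).
#' @param method_weights Named non-negative weights giving the method mix;
#'   names must be a subset of the default method portfolio (see
#'   [default_method_specs()]).
#' @param base_services Expected total services in the first year.
#' @param growth Annual growth rate of services (> -1).
#' @param noise_sd Lognormal noise sd on service counts (0 = exact trend).
#' @param profile Named vector `c(adopters=, continuers=, changers=)`.
#' @param wra0 WRA in the first demography year.
#' @param wra_growth Annual WRA growth rate (> -1).
#' @param e0_range Life expectancy at the first and last demography year
#'   (linear in between).
#' @param prop_in_union Proportion of WRA in union.
#' @param median_age_sterilisation Median age at sterilisation.
#' @param demography_extra Extra demography years beyond the history (so
#'   trends and cohort projections have denominators).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A list of class `fixture_params`.
#' @export
fixture_params <- function(n_years = 10, start_year = 2000L,
                           method_weights = c(iud10 = 1, implant3 = 2,
                                              female_sterilisation = 0.5,
                                              pill = 30, injectable = 8,
                                              condom = 40),
                           base_services = 20000, growth = 0.2,
                           noise_sd = 0.1,
                           profile = c(adopters = 0.25, continuers = 0.5,
                                       changers = 0.25),
                           wra0 = 5e6, wra_growth = 0.025,
                           e0_range = c(58, 66), prop_in_union = 0.7,
                           median_age_sterilisation = 32,
                           demography_extra = 10L, seed = 1L) {
  stopifnot(n_years >= 1, start_year >= 1982L, growth > -1, wra_growth > -1,
            all(method_weights >= 0), base_services >= 0, noise_sd >= 0,
            all(profile >= 0), abs(sum(profile) - 1) < 1e-6,
            length(e0_range) == 2L, all(e0_range > 0))
  structure(as.list(environment()), class = "fixture_params")
}

#' Generate a synthetic service history
#'
#' Seeded, reproducible multi-year multi-method history following the
#' requested growth trend with lognormal noise. The history includes
#' pre-baseline years by construction (use the early years as history and
#' the later ones as the trend), so pre-existing cohorts exist.
#'
#' @param params A [fixture_params()].
#' @return A [service_history()].
#' @export
generate_service_history <- function(params) {
  stopifnot(inherits(params, "fixture_params"))
  set.seed(params$seed)
  w <- params$method_weights / sum(params$method_weights)
  years <- seq.int(params$start_year, length.out = params$n_years)
  rows <- expand.grid(year = years, method = names(w),
                      stringsAsFactors = FALSE)
  trend <- params$base_services * (1 + params$growth)^(rows$year - params$start_year)
  noise <- if (params$noise_sd > 0)
    exp(stats::rnorm(nrow(rows), -params$noise_sd^2 / 2, params$noise_sd))
  else 1
  units <- trend * w[rows$method] * noise
  service_history(rows$year, rows$method, round(units, 2))
}

#' Generate a synthetic assumption set
#'
#' Internally consistent methods (monotone CCR tables from the bundled
#' defaults), a demographic series covering the history plus
#' `demography_extra` years, and a compact two-level toy life table, all
#' derived deterministically from the parameters.
#'
#' @param params A [fixture_params()].
#' @param cpr_basis CPR denominator basis.
#' @return An [assumption_set()].
#' @export
generate_assumption_set <- function(params, cpr_basis = "all-women") {
  stopifnot(inherits(params, "fixture_params"))
  years <- seq.int(params$start_year,
                   params$start_year + params$n_years - 1L + params$demography_extra)
  k <- seq_along(years) - 1L
  e0 <- seq(params$e0_range[1], params$e0_range[2], length.out = length(years))
  demo <- demographic_series(years, params$wra0 * (1 + params$wra_growth)^k,
                             rep(params$prop_in_union, length(years)), e0)
  lt <- toy_life_table()
  methods <- default_method_specs()
  methods <- methods[names(methods) %in% names(params$method_weights)]
  assumption_set(methods, demo, lt,
                 median_age_sterilisation = params$median_age_sterilisation,
                 cpr_basis = cpr_basis)
}

# Two-level toy life table: adult female survival at e0 50 and 75,
# worsening with age; linear interpolation spans everything in between.
toy_life_table <- function() {
  starts <- seq(15, 50, by = 5)
  lo <- 0.975 - 0.004 * seq_along(starts)   # e0 = 50 level
  hi <- 0.995 - 0.0015 * seq_along(starts)  # e0 = 75 level
  life_table_family("toy-two-level", data.frame(
    e0_level = rep(c(50, 75), each = length(starts)),
    age_group_start = rep(starts, 2L),
    p5x = c(lo, hi)))
}

#' Bundled small worked example
#'
#' A deterministic input set shaped like a real programme at roughly
#' 1/100 scale: fifteen years of mixed-method service history, a growing
#' WRA denominator, and a single-year client profile (22.4% adopters,
#' 49.2% continuers, 28.4% provider changers) to be broadcast across the
#' trend. Used in documentation and as a regression snapshot in the test
#' suite.
#'
#' @return A list with `history`, `assumptions`, `profile`, and the
#'   conventional trend window `y_start`/`y_end`.
#' @export
toy_example <- function() {
  params <- fixture_params(n_years = 15, start_year = 1996L,
                           base_services = 300, growth = 0.25,
                           noise_sd = 0, wra0 = 50000, wra_growth = 0.028,
                           e0_range = c(58, 63.5),
                           demography_extra = 6L, seed = 42L)
  history <- generate_service_history(params)
  assumptions <- generate_assumption_set(params, cpr_basis = "all-women")
  profile <- client_profile(2010L, adopters = 0.224, continuers = 0.492,
                            changers = 0.284)
  list(history = history, assumptions = assumptions, profile = profile,
       y_start = 2005L, y_end = 2010L)
}
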