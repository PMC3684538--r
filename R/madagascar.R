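#' Published Impact 2 user estimates for Marie Stopes Madagascar
#'
#' The published Impact 2 case study for Marie Stopes Madagascar,
#' 2005-2011 (condoms excluded): per-year modelled total, LAPM and
#' short-term users, clients served, adopters served, and adopters
#' counted as increasing the CPR. These are the model *outputs* published
#' for that programme, bundled as reference data; the per-method service
#' history and country default assumptions behind them are not
#' redistributed with this package, so they serve as a benchmark table,
#' not as reproducible inputs.
#'
#' @return A `data.frame` with columns `year`, `total_users`,
#'   `lapm_users`, `short_term_users`, `users_served`, `adopters_served`,
#'   `adopters_increasing_cpr`.
#' @export
madagascar_published_users <- function() {
  utils::read.csv(system.file("extdata", "madagascar",
                              "published_users_2005_2011.csv",
                              package = "fpimpact", mustWork = TRUE))
}

#' Published Marie Stopes Madagascar client profile (2011)
#'
#' The client profile measured by 2011 exit interviews (n = 438) and used
#' as a proxy for all trend years: 22.4% adopters, 49.2% continuers,
#' 28.4% provider changers.
#'
#' @param year Calendar year to attach (default 2011).
#' @return A single-year [client_profile()].
#' @export
madagascar_client_profile <- function(year = 2011L) {
  client_profile(year, adopters = 0.224, continuers = 0.492,
                 changers = 0.284)
}

#' Published Madagascar benchmark results
#'
#' Headline results published for the Marie Stopes Madagascar 2005-2011
#' Impact 2 run: the 2004 baseline contribution (0.5 percentage points of
#' WRA), the cumulative 2005-2011 contribution to increasing the modern
#' CPR (1.2 percentage points), the 2011 modelled total users (197,860)
#' and the 2011 LAPM services recorded (67,111). `desk_scale` is FALSE
#' for all of them: recomputing these requires the organisation's
#' per-method service history and the country default assumptions (UN WRA
#' projections, national CCR tables, the assigned model life-table
#' family), which are not bundled. They are provided so that users who do
#' hold those inputs can check a run against the published figures.
#'
#' @return A `data.frame` with columns `quantity`, `value`, `unit`,
#'   `desk_scale`.
#' @export
madagascar_benchmarks <- function() {
  pub <- madagascar_published_users()
  data.frame(
    quantity = c("baseline_cpr_contribution", "cumulative_pct_point_increase",
                 "total_users_2011", "lapm_services_2011"),
    value = c(0.5, 1.2, pub$total_users[pub$year == 2011], 67111),
    unit = c("percentage points", "percentage points", "women", "services"),
    desk_scale = FALSE)
}
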