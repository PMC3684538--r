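#' Virtual cohort trajectory for a long-acting method
#'
#' Services provided in one year create a cohort whose modelled user count
#' in year-offset `n` is `services * mean(CCR_n, CCR_{n+1})`: averaging
#' adjacent continuation rates credits mid-year discontinuers with half a
#' year of use. The trajectory covers `n = 0 .. max_duration - 1`; from
#' `n = max_duration` onward the whole cohort is removed. Mortality is not
#' applied to IUD/implant cohorts; discontinuation alone thins them.
#'
#' @param services Number of services provided (insertions) in the cohort
#'   year; non-negative.
#' @param method A long-acting [method_spec()].
#' @return Named numeric vector of modelled users, names are year offsets
#'   `0 .. max_duration - 1`.
#' @examples
#' m <- method_spec("toy", "long-acting", max_duration = 5,
#'                  ccr = c(1, .8, .6, .4, .2, 0))
#' longacting_cohort(100, m)  # 90 70 50 30 10
#' @export
longacting_cohort <- function(services, method) {
  stopifnot(inherits(method, "method_spec"))
  if (method$category != "long-acting")
    stop("'", method$name, "' is not a long-acting method")
  if (services < 0) stop("`services` must be non-negative")
  n <- seq_len(method$max_duration) - 1L
  traj <- services * (method$ccr[n + 1L] + method$ccr[n + 2L]) / 2
  names(traj) <- n
  traj
}

#' Virtual cohort trajectory for a sterilisation cohort
#'
#' Sterilisation protects until the cohort ages out of the reproductive
#' span, so the cohort is thinned only by mortality. Survival is applied
#' recursively, year on year: the first-year count is
#' `services * (5px)^(1/5)` at the median age of sterilisation, and each
#' subsequent year multiplies the previous year's count by the annualised
#' survival at the cohort's current median age, using the life-table level
#' implied by the `e0` projected for that calendar year. The cohort is
#' removed once its median age passes 49 (ages 15-49 count as reproductive
#' age), or at `horizon` if that comes first.
#'
#' @param services Sterilisation procedures performed in `start_year`.
#' @param start_year Calendar year of provision.
#' @param assumptions An [assumption_set()].
#' @param horizon Last calendar year to model (default: last year of the
#'   demographic series). Needed years missing from the series are an
#'   error.
#' @return Named numeric vector of modelled users by year offset, starting
#'   at 0.
#' @export
sterilisation_cohort <- function(services, start_year, assumptions, horizon = NULL) {
  if (services < 0) stop("`services` must be non-negative")
  if (is.null(horizon)) horizon <- max(assumptions$demography$year)
  age0 <- assumptions$median_age_sterilisation
  offsets <- 0:min(floor(49 - age0), horizon - start_year)
  if (length(offsets) == 0L || offsets[1] != 0L) return(stats::setNames(numeric(0), character(0)))
  traj <- numeric(length(offsets))
  u <- services
  for (i in seq_along(offsets)) {
    n <- offsets[i]
    e0 <- e0_for_year(assumptions, start_year + n)
    s <- annual_survival(survival_5px(assumptions$life_table, e0, age0 + n))
    u <- u * s
    traj[i] <- u
  }
  names(traj) <- offsets
  traj
}

#' Short-term method users from commodity counts
#'
#' Short-term commodities (pill cycles, injectable doses, condoms) confer
#' no protection beyond the year of provision, so a year's users are
#' simply the commodities distributed divided by the units needed for one
#' full year of coverage. This is deliberately conservative: 13 pill
#' cycles count as one fully covered user-year, never as 13 part-year
#' users.
#'
#' @param services Commodity units distributed; non-negative.
#' @param method A short-term [method_spec()].
#' @return Modelled users (fractional counts are kept).
#' @export
shortterm_users <- function(services, method) {
  stopifnot(inherits(method, "method_spec"))
  if (method$category != "short-term")
    stop("'", method$name, "' is not a short-term method")
  if (services < 0) stop("`services` must be non-negative")
  if (is.null(method$units_per_year) || method$units_per_year <= 0)
    stop("`units_per_year` missing or zero for '", method$name, "'")
  services / method$units_per_year
}

#' Build the full cohort matrix from a service history
#'
#' One trajectory is created per (LAPM method, provision year) with
#' positive services: long-acting cohorts via [longacting_cohort()],
#' sterilisation cohorts via [sterilisation_cohort()]. Summing the
#' calendar-year column of the matrix gives the modelled LAPM users of
#' that year across all surviving cohorts.
#'
#' @param history A service history (see [service_history()]).
#' @param assumptions An [assumption_set()].
#' @param horizon Last calendar year of interest (default: last demography
#'   year). Trajectories are truncated there; results for years up to the
#'   horizon are unaffected.
#' @return A long-format `data.frame` of class `cohort_matrix` with
#'   columns `method`, `provision_year`, `year`, `users`.
#' @export
build_cohort_matrix <- function(history, assumptions, horizon = NULL) {
  stopifnot(inherits(history, "service_history"))
  if (is.null(horizon)) horizon <- max(assumptions$demography$year)
  lapm <- lapm_methods(assumptions)
  unknown <- setdiff(unique(history$method), names(assumptions$methods))
  if (length(unknown))
    stop("unknown method(s) ", paste(sQuote(unknown), collapse = ", "),
         " in service history; known methods: ",
         paste(names(assumptions$methods), collapse = ", "))
  rows <- history[history$method %in% lapm & history$units > 0, , drop = FALSE]
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    m <- get_method(assumptions, rows$method[i])
    traj <- if (m$category == "long-acting")
      longacting_cohort(rows$units[i], m)
    else
      sterilisation_cohort(rows$units[i], rows$year[i], assumptions, horizon)
    if (!length(traj)) next
    off <- as.integer(names(traj))
    keep <- rows$year[i] + off <= horizon
    if (!any(keep)) next
    out[[i]] <- data.frame(method = rows$method[i],
                           provision_year = rows$year[i],
                           year = rows$year[i] + off[keep],
                           users = unname(traj[keep]))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  res <- if (length(out)) do.call(rbind, out)
  else data.frame(method = character(), provision_year = integer(),
                  year = integer(), users = numeric())
  attr(res, "horizon") <- horizon
  class(res) <- c("cohort_matrix", "data.frame")
  res
}

# Column sum of the cohort matrix for one calendar year, optionally
# restricted to cohorts provided up to `max_provision_year`.
cohort_column_sum <- function(matrix, year, exclude = character(),
                              max_provision_year = NULL) {
  keep <- matrix$year == year & !(matrix$method %in% exclude)
  if (!is.null(max_provision_year))
    keep <- keep & matrix$provision_year <= max_provision_year
  sub <- matrix[keep, , drop = FALSE]
  if (!nrow(sub)) return(stats::setNames(numeric(0), character(0)))
  tapply(sub$users, sub$method, sum)
}

#' Modelled users in one calendar year
#'
#' The LAPM side is the cohort-matrix column sum for `year` (all cohorts
#' still alive, whatever their provision year); the short-term side
#' divides that year's commodities by units-per-year. Methods in
#' `exclude` (condoms by default, to avoid wastage and dual-protection
#' overcounting) contribute zero.
#'
#' @param matrix A [build_cohort_matrix()] result covering `year`.
#' @param history The service history.
#' @param year Calendar year of interest.
#' @param assumptions An [assumption_set()].
#' @param exclude Character vector of method names contributing zero.
#' @return A list with `year`, named vector `by_method`, and the `lapm`,
#'   `short_term` and `total` user counts.
#' @export
users_in_year <- function(matrix, history, year, assumptions,
                          exclude = "condom") {
  lapm_by_m <- cohort_column_sum(matrix, year, exclude)
  st <- setdiff(shortterm_methods(assumptions), exclude)
  st_by_m <- vapply(st, function(mn) {
    u <- history$units[history$year == year & history$method == mn]
    shortterm_users(if (length(u)) sum(u) else 0, get_method(assumptions, mn))
  }, numeric(1))
  by_method <- c(lapm_by_m, st_by_m)
  list(year = year, by_method = by_method,
       lapm = sum(lapm_by_m), short_term = sum(st_by_m),
       total = sum(by_method))
}

#' Modelled user table across years
#'
#' Convenience wrapper applying [users_in_year()] to a span of years.
#'
#' @inheritParams users_in_year
#' @param years Calendar years to tabulate.
#' @return A `data.frame` with columns `year`, `lapm`, `short_term`,
#'   `total`.
#' @export
user_estimates <- function(history, assumptions, years, exclude = "condom",
                           matrix = NULL) {
  if (is.null(matrix))
    matrix <- build_cohort_matrix(history, assumptions, horizon = max(years))
  rows <- lapply(years, function(y) {
    u <- users_in_year(matrix, history, y, assumptions, exclude)
    data.frame(year = y, lapm = u$lapm, short_term = u$short_term,
               total = u$total)
  })
  do.call(rbind, rows)
}

#' First-year users created by one year's services
#'
#' New users in the year of provision: long-acting services are discounted
#' by `mean(CCR_0, CCR_1)` (some discontinue within the year),
#' sterilisations by one year of survival at the median age of
#' sterilisation, and short-term commodities are divided by
#' units-per-year. First-year LAPM users are therefore slightly fewer
#' than clients served.
#'
#' @param services_by_method Named numeric vector of services in one year.
#' @param year Calendar year of provision (needed for the sterilisation
#'   survival lookup).
#' @param assumptions An [assumption_set()].
#' @return Named numeric vector of new users per method.
#' @export
first_year_users <- function(services_by_method, year, assumptions) {
  if (any(services_by_method < 0)) stop("services must be non-negative")
  out <- vapply(names(services_by_method), function(mn) {
    m <- get_method(assumptions, mn)
    s <- services_by_method[[mn]]
    switch(m$category,
      "long-acting" = s * (get_ccr(m, 0L) + get_ccr(m, 1L)) / 2,
      "permanent" = {
        e0 <- e0_for_year(assumptions, year)
        s * annual_survival(survival_5px(assumptions$life_table, e0,
                                         assumptions$median_age_sterilisation))
      },
      "short-term" = shortterm_users(s, m))
  }, numeric(1))
  stats::setNames(out, names(services_by_method))
}

#' Couple-years of protection delivered
#'
#' The conventional CYP output metric, reported alongside user estimates
#' for comparison only: services per method times the method's CYP factor,
#' summed. Unlike modelled users, CYPs from long-acting methods are
#' realised over an undefined span of future years and cannot be read as
#' users in any one year.
#'
#' @param services_by_method Named numeric vector of services.
#' @param assumptions An [assumption_set()]; every method with services
#'   must carry a `cyp_factor`.
#' @return Total couple-years of protection.
#' @export
cyp_total <- function(services_by_method, assumptions) {
  if (!length(services_by_method)) return(0)
  sum(vapply(names(services_by_method), function(mn) {
    m <- get_method(assumptions, mn)
    if (is.null(m$cyp_factor))
      stop("no CYP factor for method '", mn, "'")
    services_by_method[[mn]] * m$cyp_factor
  }, numeric(1)))
}
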