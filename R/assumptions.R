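#' Define a contraceptive method
#'
#' A method specification carries everything the user-estimation engine
#' needs to know about one contraceptive method. Long-acting methods
#' (IUDs, implants) carry a cumulative continuation rate (CCR) table and a
#' maximum duration of use; permanent methods (male/female sterilisation)
#' carry nothing extra because their cohorts are thinned by life-table
#' survival; short-term methods (pills, condoms, injectables) carry the
#' number of commodity units needed for one full year of coverage.
#'
#' The CCR table gives `ccr[n + 1]` = probability that a woman is still
#' using the method `n` years after insertion, for `n = 0 .. max_duration`.
#' `CCR_0` is always 1 (every woman is using at insertion) and the table
#' must be non-increasing. A table supplied without the terminal entry at
#' `n = max_duration` is padded with 0, consistent with the whole cohort
#' being removed when the maximum duration is reached.
#'
#' @param name Method name (unique within an assumption set).
#' @param category One of `"long-acting"`, `"permanent"`, `"short-term"`.
#' @param max_duration Maximum duration of use in years (long-acting only).
#' @param ccr Numeric vector of cumulative continuation rates
#'   `CCR_0 .. CCR_max_duration` (long-acting only).
#' @param units_per_year Commodity units needed for one year of coverage
#'   (short-term only), e.g. 13 pill cycles.
#' @param cyp_factor Optional couple-years-of-protection factor per unit,
#'   used only by [cyp_total()] for comparison reporting.
#' @return An object of class `method_spec`.
#' @examples
#' method_spec("iud10", "long-acting", max_duration = 10,
#'             ccr = c(1, .88, .79, .72, .66, .61, .57, .53, .49, .45, .41))
#' method_spec("pill", "short-term", units_per_year = 13, cyp_factor = 1 / 15)
#' @export
method_spec <- function(name, category = c("long-acting", "permanent", "short-term"),
                        max_duration = NULL, ccr = NULL,
                        units_per_year = NULL, cyp_factor = NULL) {
  category <- match.arg(category)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (category == "long-acting") {
    if (is.null(max_duration) || is.null(ccr))
      stop("long-acting method '", name, "' needs `max_duration` and `ccr`")
    max_duration <- as.integer(max_duration)
    if (max_duration < 1L) stop("`max_duration` must be >= 1")
    if (length(ccr) == max_duration) ccr <- c(ccr, 0)  # missing terminal entry -> 0
    if (length(ccr) != max_duration + 1L)
      stop("`ccr` for '", name, "' must have max_duration + 1 = ",
           max_duration + 1L, " entries (CCR_0 .. CCR_max)")
    if (abs(ccr[1L] - 1) > 1e-12)
      stop("CCR_0 must equal 1 for '", name, "'")
    if (any(ccr < 0 | ccr > 1)) stop("CCR values for '", name, "' must lie in [0, 1]")
    if (any(diff(ccr) > 1e-12)) stop("CCR table for '", name, "' must be non-increasing")
    if (!is.null(units_per_year))
      stop("`units_per_year` does not apply to long-acting method '", name, "'")
  } else if (category == "short-term") {
    if (is.null(units_per_year) || units_per_year <= 0)
      stop("short-term method '", name, "' needs `units_per_year` > 0")
    if (!is.null(max_duration) || !is.null(ccr))
      stop("`max_duration`/`ccr` do not apply to short-term method '", name, "'")
  } else { # permanent
    if (!is.null(max_duration) || !is.null(ccr) || !is.null(units_per_year))
      stop("permanent method '", name, "' takes no duration, CCR or units fields")
  }
  if (!is.null(cyp_factor) && cyp_factor <= 0) stop("`cyp_factor` must be positive")
  structure(
    list(name = name, category = category,
         max_duration = if (category == "long-acting") max_duration else NULL,
         ccr = if (category == "long-acting") as.numeric(ccr) else NULL,
         units_per_year = if (category == "short-term") as.numeric(units_per_year) else NULL,
         cyp_factor = if (is.null(cyp_factor)) NULL else as.numeric(cyp_factor)),
    class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat("<method_spec> ", x$name, " [", x$category, "]\n", sep = "")
  if (x$category == "long-acting")
    cat("  max duration:", x$max_duration, "years; CCR:",
        paste(signif(x$ccr, 3), collapse = ", "), "\n")
  if (x$category == "short-term")
    cat("  units per year of coverage:", x$units_per_year, "\n")
  if (!is.null(x$cyp_factor)) cat("  CYP factor:", x$cyp_factor, "\n")
  invisible(x)
}

#' Cumulative continuation rate lookup
#'
#' Returns `CCR_n` for a long-acting method: the probability that a user is
#' still on the method `n` years after insertion. Offsets beyond the
#' maximum duration are an error because the whole cohort has already been
#' removed from the model by then.
#'
#' @param method A long-acting [method_spec()].
#' @param n Integer year offset, `0 <= n <= max_duration`.
#' @return The continuation rate (`n = 0` always returns 1).
#' @export
get_ccr <- function(method, n) {
  stopifnot(inherits(method, "method_spec"))
  if (method$category != "long-acting")
    stop("CCR tables only apply to long-acting methods, not '", method$name, "'")
  n <- as.integer(n)
  if (n < 0L || n > method$max_duration)
    stop("CCR offset n = ", n, " outside 0..", method$max_duration,
         " for '", method$name, "' (cohort already removed)")
  method$ccr[n + 1L]
}

#' Demographic series
#'
#' Per-calendar-year demographic inputs: the number of women of
#' reproductive age (WRA, the CPR denominator), the proportion of WRA in
#' union (used when the CPR basis is in-union women), and the projected
#' female life expectancy at birth `e0` (used to pick a model life-table
#' level for sterilisation cohort survival).
#'
#' @param year Integer calendar years (need not be contiguous for `e0`
#'   anchor purposes, but every modelled year must be present for `wra`).
#' @param wra Women of reproductive age (15-49) per year; positive.
#' @param prop_in_union Proportion of WRA in union, in `[0, 1]`.
#' @param e0 Projected female life expectancy at birth, years.
#' @return A `data.frame` of class `demographic_series`.
#' @export
demographic_series <- function(year, wra, prop_in_union, e0) {
  year <- as.integer(year)
  stopifnot(length(wra) == length(year), length(prop_in_union) == length(year),
            length(e0) == length(year))
  if (anyDuplicated(year)) stop("duplicate years in demographic series")
  if (any(wra <= 0)) stop("`wra` must be positive for every modelled year")
  if (any(prop_in_union < 0 | prop_in_union > 1))
    stop("`prop_in_union` must lie in [0, 1]")
  if (any(e0 <= 0)) stop("`e0` must be positive")
  out <- data.frame(year = year, wra = as.numeric(wra),
                    prop_in_union = as.numeric(prop_in_union),
                    e0 = as.numeric(e0))
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("demographic_series", "data.frame")
  out
}

#' Life-table family of survival anchors
#'
#' A small anchor table standing in for one of the nine model life-table
#' families (Coale-Demeny East/North/South/West, UN Chilean, UN Far East
#' Asian, UN General, UN Latin, UN South Asian): for each anchor level of
#' female life expectancy at birth `e0`, the five-year survival
#' probability `5px` for each five-year age group. The engine interpolates
#' linearly in `e0` between anchor levels; this keeps the package free of
#' a full Coale-Demeny/UN reimplementation while letting users supply
#' their country's assigned family as data.
#'
#' @param name Family name.
#' @param levels A data.frame with columns `e0_level`, `age_group_start`,
#'   `p5x`; `e0_level` anchors must be strictly increasing and every level
#'   must cover the same age groups.
#' @return An object of class `life_table_family`.
#' @export
life_table_family <- function(name, levels) {
  stopifnot(is.data.frame(levels),
            all(c("e0_level", "age_group_start", "p5x") %in% names(levels)))
  if (any(levels$p5x <= 0 | levels$p5x > 1))
    stop("5px values must lie in (0, 1]")
  lv <- sort(unique(levels$e0_level))
  if (length(lv) < 1L) stop("life table needs at least one e0 level")
  ages <- sort(unique(levels$age_group_start))
  for (l in lv) {
    got <- sort(levels$age_group_start[levels$e0_level == l])
    if (!identical(got, ages))
      stop("life-table level e0 = ", l, " does not cover the same age groups")
  }
  structure(list(name = name,
                 levels = levels[order(levels$e0_level, levels$age_group_start),
                                 c("e0_level", "age_group_start", "p5x")]),
            class = "life_table_family")
}

#' Five-year survival probability from a life-table family
#'
#' Looks up `5px`, the probability of surviving from exact age `x` to
#' `x + 5`, for the five-year age group containing `age`, at life
#' expectancy `e0`. Between anchor levels the probability is interpolated
#' linearly in `e0`; outside the anchor range it is clamped to the nearest
#' level.
#'
#' @param family A [life_table_family()].
#' @param e0 Female life expectancy at birth, years.
#' @param age Age in years; must fall in a covered age group.
#' @return The survival probability `5px`.
#' @export
survival_5px <- function(family, e0, age) {
  stopifnot(inherits(family, "life_table_family"), e0 > 0)
  lv <- family$levels
  starts <- sort(unique(lv$age_group_start))
  grp <- starts[starts <= age & age < starts + 5]
  if (length(grp) != 1L)
    stop("age ", age, " is outside the covered age groups (",
         min(starts), "-", max(starts) + 4, ") of life table '", family$name, "'")
  sub <- lv[lv$age_group_start == grp, , drop = FALSE]
  if (nrow(sub) == 1L) return(sub$p5x)
  # rule = 2 clamps to the nearest anchor level outside the e0 range
  stats::approx(sub$e0_level, sub$p5x, xout = e0, rule = 2)$y
}

#' Annualise a five-year survival probability
#'
#' The model works on annual time steps, so the standard five-year
#' life-table survival probability is converted to a one-year probability
#' as its fifth root, assuming survival is evenly distributed across the
#' age group.
#'
#' @param p5x Five-year survival probability in `(0, 1]`.
#' @return `p5x^(1/5)`.
#' @export
annual_survival <- function(p5x) {
  if (any(p5x <= 0)) stop("survival probability must be positive")
  if (any(p5x > 1)) stop("survival probability cannot exceed 1")
  p5x^(1 / 5)
}

#' Assemble a full assumption set
#'
#' Bundles the method definitions, demographic series, life-table family,
#' median age of sterilisation and the CPR basis into the single object
#' every engine function takes.
#'
#' @param methods A list of [method_spec()] objects (unique names).
#' @param demography A [demographic_series()].
#' @param life_table A [life_table_family()].
#' @param median_age_sterilisation Median age at sterilisation, years
#'   (in `[15, 49)`). Applied to male sterilisation too: the protected
#'   female partner is counted as the user, and in the absence of
#'   partner-age data her age is taken at the same median.
#' @param cpr_basis `"all-women"` or `"in-union"`: whether CPR denominators
#'   are all WRA or in-union WRA.
#' @return An object of class `assumption_set`.
#' @export
assumption_set <- function(methods, demography, life_table,
                           median_age_sterilisation = 30,
                           cpr_basis = c("all-women", "in-union")) {
  cpr_basis <- match.arg(cpr_basis)
  stopifnot(is.list(methods), length(methods) > 0L,
            inherits(demography, "demographic_series"),
            inherits(life_table, "life_table_family"))
  for (m in methods) stopifnot(inherits(m, "method_spec"))
  nms <- vapply(methods, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("method names must be unique")
  names(methods) <- nms
  if (median_age_sterilisation < 15 || median_age_sterilisation >= 49)
    stop("`median_age_sterilisation` must lie in [15, 49)")
  structure(list(methods = methods, demography = demography,
                 life_table = life_table,
                 median_age_sterilisation = median_age_sterilisation,
                 cpr_basis = cpr_basis),
            class = "assumption_set")
}

#' @export
print.assumption_set <- function(x, ...) {
  cat("<assumption_set>\n  methods: ", paste(names(x$methods), collapse = ", "),
      "\n  demography: ", min(x$demography$year), "-", max(x$demography$year),
      "\n  life table: ", x$life_table$name,
      "\n  median age of sterilisation: ", x$median_age_sterilisation,
      "\n  CPR basis: ", x$cpr_basis, "\n", sep = "")
  invisible(x)
}

get_method <- function(assumptions, name) {
  m <- assumptions$methods[[name]]
  if (is.null(m))
    stop("unknown method '", name, "'; known methods: ",
         paste(names(assumptions$methods), collapse = ", "))
  m
}

lapm_methods <- function(assumptions) {
  cats <- vapply(assumptions$methods, `[[`, "", "category")
  names(assumptions$methods)[cats %in% c("long-acting", "permanent")]
}

shortterm_methods <- function(assumptions) {
  cats <- vapply(assumptions$methods, `[[`, "", "category")
  names(assumptions$methods)[cats == "short-term"]
}

#' Life expectancy at birth for a calendar year
#'
#' `e0` for years between the supplied demographic anchor points is
#' interpolated linearly in calendar year; years outside the series range
#' are an error because the sterilisation survival lookup would otherwise
#' silently extrapolate mortality.
#'
#' @param assumptions An [assumption_set()].
#' @param year Calendar year.
#' @return `e0` in years.
#' @export
e0_for_year <- function(assumptions, year) {
  d <- assumptions$demography
  if (year < min(d$year) || year > max(d$year))
    stop("demographic series does not cover year ", year,
         " (covers ", min(d$year), "-", max(d$year), ")")
  stats::approx(d$year, d$e0, xout = year)$y
}

#' CPR denominator for a calendar year
#'
#' Women of reproductive age in `year`, restricted to in-union women when
#' the assumption set's CPR basis is `"in-union"`.
#'
#' @param assumptions An [assumption_set()].
#' @param year Calendar year; must be present in the demographic series.
#' @return The denominator count.
#' @export
cpr_denominator <- function(assumptions, year) {
  d <- assumptions$demography
  i <- match(year, d$year)
  if (is.na(i))
    stop("demographic series has no entry for year ", year)
  if (assumptions$cpr_basis == "in-union") d$wra[i] * d$prop_in_union[i] else d$wra[i]
}
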