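#' Client profile: adopters, continuers, provider changers
#'
#' The per-year split of an organisation's clients into adopters (not
#' using any modern method before being served), continuers (already using
#' a method obtained from this organisation) and provider changers
#' (already using a method obtained elsewhere). Provider changers are the
#' substitution effect: they are already counted in the national CPR and
#' never credit the organisation. The three proportions must sum to 1.
#'
#' @param year Integer calendar years.
#' @param adopters,continuers,changers Proportions in `[0, 1]`, summing to
#'   1 within each year (recycled if scalar).
#' @return A `data.frame` of class `client_profile`.
#' @export
client_profile <- function(year, adopters, continuers, changers) {
  year <- as.integer(year)
  n <- length(year)
  adopters <- rep_len(adopters, n); continuers <- rep_len(continuers, n)
  changers <- rep_len(changers, n)
  if (anyDuplicated(year)) stop("duplicate years in client profile")
  if (any(c(adopters, continuers, changers) < 0) ||
      any(c(adopters, continuers, changers) > 1))
    stop("profile proportions must lie in [0, 1]")
  if (any(abs(adopters + continuers + changers - 1) > 1e-6))
    stop("profile proportions must sum to 1 in every year")
  out <- data.frame(year = year, adopters = adopters,
                    continuers = continuers, changers = changers)
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("client_profile", "data.frame")
  out
}

# Return the profile covering exactly `years`. A single-year profile is
# broadcast to all years (the usual proxy when only one exit-interview
# survey exists), with a warning; gaps otherwise are an error.
broadcast_profile <- function(profile, years) {
  stopifnot(inherits(profile, "client_profile"))
  if (all(years %in% profile$year))
    return(profile[match(years, profile$year), , drop = FALSE])
  if (nrow(profile) == 1L) {
    warning("single-year client profile applied to all ", length(years),
            " trend years as a proxy", call. = FALSE)
    out <- profile[rep(1L, length(years)), , drop = FALSE]
    out$year <- as.integer(years)
    rownames(out) <- NULL
    return(out)
  }
  stop("client profile missing year(s) ",
       paste(setdiff(years, profile$year), collapse = ", "))
}

#' Baseline CPR contribution (step 1)
#'
#' The baseline year `y0` is the year before the trend starts. Baseline
#' users are all modelled users in `y0` (LAPM cohorts from the whole
#' history plus that year's short-term users); the baseline CPR
#' contribution divides them by the `y0` denominator (all or in-union
#' WRA). Subsequent years must first maintain this contribution — in both
#' absolute users and, through the growing denominator, population-growth
#' offsets — before anything counts as increase.
#'
#' @param history A [service_history()] reaching up to `y0`.
#' @param assumptions An [assumption_set()].
#' @param y0 Baseline calendar year.
#' @param exclude Methods contributing zero (default condoms).
#' @param matrix Optional pre-built cohort matrix covering `y0`.
#' @return A list of class `cpr_baseline`: `y0`, `users`, `denominator`,
#'   `contribution` (fraction of WRA).
#' @export
compute_baseline <- function(history, assumptions, y0, exclude = "condom",
                             matrix = NULL) {
  if (is.null(matrix))
    matrix <- build_cohort_matrix(history, assumptions, horizon = y0)
  u <- users_in_year(matrix, history, y0, assumptions, exclude)
  den <- cpr_denominator(assumptions, y0)
  structure(list(y0 = y0, users = u$total, denominator = den,
                 contribution = u$total / den),
            class = "cpr_baseline")
}

#' Pre-existing LAPM users across the trend (step 2)
#'
#' Users in each trend year from LAPM cohorts provided in the baseline
#' year or earlier: women served in the past who are modelled as still
#' using their method. They count toward the CPR every year without any
#' client-profile discounting, since they were already credited at
#' baseline.
#'
#' @param history A [service_history()].
#' @param assumptions An [assumption_set()].
#' @param years Trend years (all `> y0`).
#' @param y0 Baseline year.
#' @param exclude Methods contributing zero.
#' @param matrix Optional pre-built cohort matrix covering `max(years)`.
#' @return Named numeric vector of pre-existing users per trend year.
#' @export
pre_existing_series <- function(history, assumptions, years, y0,
                                exclude = "condom", matrix = NULL) {
  if (is.null(matrix))
    matrix <- build_cohort_matrix(history, assumptions, horizon = max(years))
  out <- vapply(years, function(y)
    sum(cohort_column_sum(matrix, y, exclude, max_provision_year = y0)),
    numeric(1))
  stats::setNames(out, years)
}

#' Users needed to maintain last year's CPR count (steps 4 and 7)
#'
#' The gap that this year's new users must fill before any increase is
#' possible: last year's total users counting in the CPR, minus the
#' pre-existing and existing users already carried into this year.
#' Clamped at zero — when carried-over users alone exceed last year's
#' total there is nothing to maintain.
#'
#' @param previous_total Total users counting in CPR the year before
#'   (baseline users for the first trend year).
#' @param pre_existing,existing This year's carried-over users.
#' @return The non-negative maintenance requirement.
#' @export
users_needed_to_maintain <- function(previous_total, pre_existing, existing) {
  stopifnot(previous_total >= 0, pre_existing >= 0, existing >= 0)
  max(0, previous_total - pre_existing - existing)
}

#' Allocate new users between maintaining and increasing (step 4)
#'
#' New users split by the client profile into continuers
#' (`C = new * pct_continuers`) and adopters (`A = new * pct_adopters`);
#' provider changers are never allocated. Three situations:
#'
#' * Situation 1 — `C >= needed`: continuers alone maintain the previous
#'   level; every adopter increases user numbers. Continuers beyond
#'   `needed` are surplus and are not counted (`dropped_continuers`).
#' * Situation 2 — `C + A <= needed`: even continuers plus adopters fall
#'   short; all maintain, nothing increases.
#' * Situation 3 — otherwise: all continuers plus some adopters maintain;
#'   the remaining adopters increase.
#'
#' @param needed Users needed to maintain (from
#'   [users_needed_to_maintain()]).
#' @param new_users Total new users this year.
#' @param profile_slice One row of a [client_profile()] (or a list with
#'   `adopters`, `continuers`, `changers`).
#' @return A list of class `cpr_allocation`: `situation` (1, 2 or 3),
#'   `maintain`, `increase`, `new_continuers`, `new_adopters`,
#'   `dropped_continuers`.
#' @export
allocate_new_users <- function(needed, new_users, profile_slice) {
  stopifnot(needed >= 0, new_users >= 0)
  a <- profile_slice$adopters; c_ <- profile_slice$continuers
  p <- profile_slice$changers
  if (any(c(a, c_, p) < 0) || any(c(a, c_, p) > 1) ||
      abs(a + c_ + p - 1) > 1e-6)
    stop("invalid client profile proportions")
  C <- new_users * c_
  A <- new_users * a
  if (C >= needed) {
    alloc <- list(situation = 1L, maintain = needed, increase = A,
                  dropped_continuers = C - needed)
  } else if (C + A <= needed) {
    alloc <- list(situation = 2L, maintain = C + A, increase = 0,
                  dropped_continuers = 0)
  } else {
    alloc <- list(situation = 3L, maintain = needed,
                  increase = A - (needed - C), dropped_continuers = 0)
  }
  structure(c(alloc, list(new_continuers = C, new_adopters = A)),
            class = "cpr_allocation")
}

#' Proportion of new users counting in the CPR (step 5)
#'
#' The counted fraction of a year's new users: those maintaining plus
#' those increasing, over all new users. Provider changers (and, in
#' situation 1, surplus continuers) fall out here. Defined as 0 when
#' there are no new users.
#'
#' @param allocation A [allocate_new_users()] result.
#' @param new_users Total new users the allocation was computed from.
#' @return A fraction in `[0, 1]`.
#' @export
counting_fraction <- function(allocation, new_users) {
  stopifnot(new_users >= 0)
  if (new_users == 0) return(0)
  (allocation$maintain + allocation$increase) / new_users
}

#' Project counted LAPM cohorts into later trend years (step 6)
#'
#' New LAPM users counted in the CPR in their provision year continue
#' into later years as "existing users". Because all cohort formulas are
#' linear in services, the counted sub-cohort is obtained by scaling the
#' full method trajectory by the year's counting fraction; only offsets
#' `>= 1` contribute (the provision year itself counts them as new
#' users).
#'
#' @param lapm_services_by_method Named services vector (LAPM methods
#'   only) for the provision year.
#' @param provision_year Calendar year of provision.
#' @param fraction Counting fraction of that year.
#' @param assumptions An [assumption_set()].
#' @param years Later calendar years to project into.
#' @return Named numeric vector of existing users per requested year.
#' @export
project_existing_users <- function(lapm_services_by_method, provision_year,
                                   fraction, assumptions, years) {
  out <- stats::setNames(numeric(length(years)), years)
  if (fraction == 0 || !length(lapm_services_by_method)) return(out)
  horizon <- if (length(years)) max(years) else provision_year
  for (mn in names(lapm_services_by_method)) {
    m <- get_method(assumptions, mn)
    traj <- if (m$category == "long-acting")
      longacting_cohort(lapm_services_by_method[[mn]], m)
    else
      sterilisation_cohort(lapm_services_by_method[[mn]], provision_year,
                           assumptions, horizon)
    off <- as.integer(names(traj))
    for (i in seq_along(off)) {
      if (off[i] < 1L) next
      y <- as.character(provision_year + off[i])
      if (y %in% names(out)) out[y] <- out[y] + fraction * traj[i]
    }
  }
  out
}

#' Run the full CPR-contribution trend (steps 1-8)
#'
#' Iterates the yearly accounting over `y_start .. y_end`, measuring each
#' year against the year immediately before it: pre-existing users
#' (cohorts provided at or before baseline), existing users (counted
#' cohorts created earlier in the trend), this year's new users, the
#' maintain/increase allocation against the previous year's total, the
#' counting fraction, and the projection of counted LAPM cohorts forward.
#' The percentage-point series (step 8) is attached via
#' [percentage_point_series()].
#'
#' @param history A [service_history()] covering baseline and trend years
#'   (further back for accurate baselines).
#' @param assumptions An [assumption_set()] whose demography covers
#'   `y_start - 1 .. y_end`.
#' @param profile A [client_profile()] covering the trend years, or a
#'   single-year profile to broadcast.
#' @param y_start,y_end First and last trend years; the baseline year is
#'   `y_start - 1`.
#' @param exclude Methods contributing zero (default condoms).
#' @return A list of class `cpr_trend`: `baseline`, per-year `years`
#'   data.frame (`year`, `pre_existing`, `existing`, `new_users`,
#'   `situation`, `maintain`, `increase`, `counting_fraction`,
#'   `dropped_continuers`, `total_users_in_cpr`, `total_pct_contribution`,
#'   `pct_point_increase`), and `new_cpr_users` (long per-method
#'   breakdown of counted new users).
#' @export
run_trend <- function(history, assumptions, profile, y_start, y_end,
                      exclude = "condom") {
  stopifnot(y_start <= y_end)
  y0 <- y_start - 1L
  years <- seq.int(y_start, y_end)
  profile <- broadcast_profile(profile, years)
  matrix <- build_cohort_matrix(history, assumptions, horizon = y_end)
  baseline <- compute_baseline(history, assumptions, y0, exclude,
                               matrix = matrix)
  pre <- pre_existing_series(history, assumptions, years, y0, exclude,
                             matrix = matrix)
  existing <- stats::setNames(numeric(length(years)), years)
  rows <- vector("list", length(years))
  breakdown <- vector("list", length(years))
  prev_total <- baseline$users
  for (i in seq_along(years)) {
    y <- years[i]
    svc <- services_for_year(history, y, exclude)
    new_by_m <- first_year_users(svc, y, assumptions)
    new_total <- sum(new_by_m)
    needed <- users_needed_to_maintain(prev_total, pre[i], existing[i])
    alloc <- allocate_new_users(needed, new_total, profile[i, ])
    f <- counting_fraction(alloc, new_total)
    # counted LAPM sub-cohorts become existing users in later years
    lapm <- names(svc)[vapply(names(svc), function(mn)
      get_method(assumptions, mn)$category != "short-term", TRUE)]
    if (i < length(years)) {
      later <- years[(i + 1):length(years)]
      proj <- project_existing_users(svc[lapm], y, f, assumptions, later)
      existing[(i + 1):length(years)] <-
        existing[(i + 1):length(years)] + proj
    }
    total <- pre[i] + existing[i] + alloc$maintain + alloc$increase
    rows[[i]] <- data.frame(
      year = y, pre_existing = unname(pre[i]), existing = unname(existing[i]),
      new_users = new_total, situation = alloc$situation,
      maintain = alloc$maintain, increase = alloc$increase,
      counting_fraction = f, dropped_continuers = alloc$dropped_continuers,
      new_adopters = alloc$new_adopters,
      total_users_in_cpr = total)
    if (length(new_by_m))
      breakdown[[i]] <- data.frame(year = y, method = names(new_by_m),
                                   new_users = unname(new_by_m),
                                   new_cpr_users = unname(f * new_by_m))
    prev_total <- total
  }
  trend <- structure(
    list(baseline = baseline, years = do.call(rbind, rows),
         new_cpr_users = do.call(rbind, breakdown),
         profile = profile, exclude = exclude),
    class = "cpr_trend")
  pct <- percentage_point_series(trend, assumptions)
  trend$years$total_pct_contribution <- pct$total_pct_contribution
  trend$years$pct_point_increase <- pct$pct_point_increase
  trend
}

#' Percentage-point contribution series (step 8)
#'
#' Each year's total users counting in the CPR are divided by that year's
#' denominator (all or in-union WRA) to give the organisation's total
#' percentage-point contribution; subtracting the baseline contribution
#' isolates the percentage points of CPR *increase*. Because the
#' denominator grows with the population, constant user numbers yield a
#' shrinking contribution — the population-growth offset at work. The
#' final year's `pct_point_increase` is the cumulative increase over the
#' whole trend.
#'
#' @param trend A [run_trend()] result (or a partial one with `baseline`
#'   and `years$total_users_in_cpr`).
#' @param assumptions The [assumption_set()] used for the trend.
#' @return A `data.frame` with `year`, `total_pct_contribution` and
#'   `pct_point_increase`, both in percentage points (0-100 scale).
#' @export
percentage_point_series <- function(trend, assumptions) {
  yrs <- trend$years$year
  den <- vapply(yrs, function(y) cpr_denominator(assumptions, y), numeric(1))
  total_pct <- 100 * trend$years$total_users_in_cpr / den
  data.frame(year = yrs, total_pct_contribution = total_pct,
             pct_point_increase = total_pct - 100 * trend$baseline$contribution)
}

#' @export
print.cpr_trend <- function(x, ...) {
  cat("<cpr_trend> ", min(x$years$year), "-", max(x$years$year),
      " (baseline ", x$baseline$y0, ": ",
      format(round(x$baseline$users)), " users, ",
      sprintf("%.2f", 100 * x$baseline$contribution),
      "% of WRA)\n", sep = "")
  cat("  cumulative percentage-point increase: ",
      sprintf("%.2f", x$years$pct_point_increase[nrow(x$years)]), "\n", sep = "")
  invisible(x)
}
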