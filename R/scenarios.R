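#' Define a labelled client-profile scenario
#'
#' @param label Scenario label (e.g. "low adopters").
#' @param profile A [client_profile()].
#' @return An object of class `profile_scenario`.
#' @export
profile_scenario <- function(label, profile) {
  stopifnot(is.character(label), length(label) == 1L,
            inherits(profile, "client_profile"))
  structure(list(label = label, profile = profile),
            class = "profile_scenario")
}

#' Client-profile sensitivity sweep
#'
#' Re-runs the full trend engine once per scenario on identical service
#' and demographic inputs, varying only the client profile. This is the
#' standard way to bound the increasing-CPR estimate when the profile is
#' known for one year only: a lower-adopter and a higher-adopter profile
#' bracket the actual one. Holding the provider-changer share fixed,
#' raising the adopter share can only raise the cumulative increase.
#'
#' @param history A [service_history()].
#' @param assumptions An [assumption_set()].
#' @param scenarios List of [profile_scenario()] objects (at least one).
#' @param y_start,y_end Trend window.
#' @param exclude Methods contributing zero (default condoms).
#' @return A list of class `profile_sweep`: `series` (data.frame
#'   `scenario`, `year`, `pct_point_increase`), `cumulative` (named
#'   final-year increase per scenario), and the per-scenario `trends`.
#' @export
profile_sweep <- function(history, assumptions, scenarios, y_start, y_end,
                          exclude = "condom") {
  stopifnot(is.list(scenarios), length(scenarios) >= 1L)
  for (s in scenarios) stopifnot(inherits(s, "profile_scenario"))
  labels <- vapply(scenarios, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("scenario labels must be unique")
  trends <- lapply(scenarios, function(s)
    run_trend(history, assumptions, s$profile, y_start, y_end, exclude))
  names(trends) <- labels
  series <- do.call(rbind, lapply(labels, function(l)
    data.frame(scenario = l, year = trends[[l]]$years$year,
               pct_point_increase = trends[[l]]$years$pct_point_increase)))
  cumulative <- vapply(trends, function(tr)
    tr$years$pct_point_increase[nrow(tr$years)], numeric(1))
  structure(list(series = series, cumulative = cumulative, trends = trends),
            class = "profile_sweep")
}

#' @export
print.profile_sweep <- function(x, ...) {
  cat("<profile_sweep> cumulative percentage-point increase by scenario:\n")
  for (l in names(x$cumulative))
    cat(sprintf("  %-20s %.3f\n", l, x$cumulative[[l]]))
  invisible(x)
}
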