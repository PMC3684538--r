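#' Service provision history
#'
#' The primary model input: services or commodities provided per calendar
#' year per method. Histories may (and for accurate baselines, should)
#' reach back to 1982 so that long-acting cohorts provided before the
#' analysis window are captured. Missing (year, method) combinations are
#' treated as zero services by every consumer.
#'
#' @param year Integer calendar years, all `>= 1982`.
#' @param method Method names (must match the assumption set when used).
#' @param units Non-negative service/commodity counts.
#' @return A `data.frame` of class `service_history` with columns `year`,
#'   `method`, `units`.
#' @export
service_history <- function(year, method, units) {
  year <- as.integer(year)
  stopifnot(length(method) == length(year), length(units) == length(year))
  if (length(year) && any(year < 1982L))
    stop("service history years must be >= 1982 (earliest cohort the model tracks)")
  if (any(units < 0)) stop("`units` must be non-negative")
  key <- paste(year, method)
  if (anyDuplicated(key))
    stop("duplicate (year, method) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  out <- data.frame(year = year, method = as.character(method),
                    units = as.numeric(units))
  out <- out[order(out$year, out$method), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("service_history", "data.frame")
  out
}

# Named services-by-method vector for one year (zeros dropped; methods
# in `exclude` dropped).
services_for_year <- function(history, year, exclude = character()) {
  sub <- history[history$year == year & !(history$method %in% exclude) &
                   history$units > 0, , drop = FALSE]
  stats::setNames(sub$units, sub$method)
}
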