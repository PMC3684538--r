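#' Canonicalise method names
#'
#' Field data files spell method names in many ways ("IUD-10yr",
#' "Copper-T (10 year)", "Female Sterilization"). Matching is
#' case-insensitive after stripping non-alphanumeric characters, with an
#' alias table mapping common spellings onto the canonical portfolio
#' names. Unrecognised names are returned lowercased-and-stripped so
#' user-defined methods still work.
#'
#' @param x Character vector of method names.
#' @return Character vector of canonical names.
#' @export
canonical_method_name <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(x))
  aliases <- c(
    iud10yr = "iud10", iud10year = "iud10", coppert = "iud10",
    coppert380a = "iud10", iud = "iud10",
    iud5yr = "iud5", iud5year = "iud5",
    implant5yr = "implant5", jadelle = "implant5",
    implant4yr = "implant4", sinoimplant = "implant4",
    implant3yr = "implant3", implanon = "implant3", implant = "implant3",
    femalesterilization = "female_sterilisation",
    femalesterilisation = "female_sterilisation",
    tuballigation = "female_sterilisation",
    malesterilization = "male_sterilisation",
    malesterilisation = "male_sterilisation",
    vasectomy = "male_sterilisation",
    pills = "pill", pill = "pill", oralcontraceptive = "pill",
    ocp = "pill", condoms = "condom", condom = "condom",
    injectables = "injectable", injectable = "injectable",
    injection = "injectable", depo = "injectable", depoprovera = "injectable",
    iud10 = "iud10", iud5 = "iud5", implant5 = "implant5",
    implant4 = "implant4", implant3 = "implant3")
  out <- unname(aliases[key])
  ifelse(is.na(out), key, out)
}

#' Read a service history from CSV
#'
#' Expects exactly the columns `year`, `method`, `units`. Thousands
#' separators in `units` ("1,234") are tolerated; method names are
#' canonicalised via [canonical_method_name()]; duplicate (year, method)
#' rows, negative units and malformed cells are errors naming the row.
#'
#' @param path CSV path.
#' @param canonicalise Map method names onto canonical portfolio names
#'   (default TRUE).
#' @return A [service_history()].
#' @export
read_service_history <- function(path, canonicalise = TRUE) {
  if (!file.exists(path)) stop("service history file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("year", "method", "units")
  if (!identical(sort(names(raw)), sort(need)))
    stop("service history must have exactly columns year, method, units; got: ",
         paste(names(raw), collapse = ", "))
  year <- suppressWarnings(as.integer(raw$year))
  units <- suppressWarnings(as.numeric(gsub("[ ,]", "", raw$units)))
  bad <- which(is.na(year) | is.na(units) | !nzchar(raw$method))
  if (length(bad))
    stop("malformed service history row(s): ",
         paste(bad + 1L, collapse = ", "), " of ", path)  # +1 for header line
  neg <- which(units < 0)
  if (length(neg))
    stop("negative units in row(s): ", paste(neg + 1L, collapse = ", "))
  method <- if (canonicalise) canonical_method_name(raw$method) else raw$method
  service_history(year, method, units)
}

#' Write a service history to CSV
#'
#' @param history A [service_history()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_service_history <- function(history, path) {
  utils::write.csv(as.data.frame(unclass(history)), path, row.names = FALSE)
  invisible(path)
}

#' Write trend results to CSV
#'
#' One row per trend year with the full decomposition (pre-existing,
#' existing, maintain, increase, counting fraction, totals and
#' percentage points), written at full precision so write-then-read is
#' lossless.
#'
#' @param trend A [run_trend()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trend_csv <- function(trend, path) {
  df <- trend$years
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Render a human-readable trend summary
#'
#' States the baseline year and contribution, the per-year decomposition,
#' the cumulative percentage-point increase, and the interpretation
#' caveat that the estimate holds only if all other providers at least
#' maintain their baseline contributions.
#'
#' @param trend A [run_trend()] result.
#' @param path Optional file to write; otherwise returns the text.
#' @return The summary text, invisibly if written to file.
#' @export
summary_report <- function(trend, path = NULL) {
  b <- trend$baseline
  y <- trend$years
  lines <- c(
    "Contribution to increasing the modern CPR",
    "==========================================",
    sprintf("Baseline year %d: %s modelled users, %.2f%% of WRA",
            b$y0, format(round(b$users), big.mark = ","),
            100 * b$contribution),
    "",
    sprintf("%-6s %12s %12s %12s %12s %10s %8s",
            "year", "pre-exist", "existing", "maintain", "increase",
            "in CPR", "pp incr"),
    sprintf("%-6d %12.0f %12.0f %12.0f %12.0f %10.0f %8.2f",
            y$year, y$pre_existing, y$existing, y$maintain, y$increase,
            y$total_users_in_cpr, y$pct_point_increase),
    "",
    sprintf("Cumulative contribution to increasing CPR, %d-%d: %.2f percentage points",
            min(y$year), max(y$year), y$pct_point_increase[nrow(y)]),
    "",
    paste("Interpretation: these figures are an increase to the national CPR",
          "only assuming all other providers at least maintain their baseline",
          "contributions; otherwise they offset another provider's decline."))
  text <- paste(lines, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}

#' Read a run configuration
#'
#' A run config (YAML or JSON) names the input files and the trend
#' window:
#' \preformatted{
#' history: services.csv
#' assumptions: assumptions.yaml
#' profile: {year: 2011, adopters: 0.224, continuers: 0.492, changers: 0.284}
#' y_start: 2005
#' y_end: 2011
#' exclude: [condom]        # optional; default condoms excluded
#' output_dir: results      # optional; default "."
#' }
#' The profile block accepts vectors for per-year profiles. Relative
#' paths resolve against the config file's directory.
#'
#' @param path Config file path.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- read_config(path)
  dir <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(dir, p)
  for (f in c("history", "assumptions")) {
    if (is.null(cfg[[f]])) stop("run config missing field: ", f)
    cfg[[f]] <- rel(cfg[[f]])
    if (!file.exists(cfg[[f]])) stop(f, " file not found: ", cfg[[f]])
  }
  if (is.null(cfg$y_start) || is.null(cfg$y_end) || cfg$y_start > cfg$y_end)
    stop("run config needs y_start <= y_end")
  p <- cfg$profile
  if (is.null(p)) stop("run config missing field: profile")
  cfg$profile <- client_profile(p$year, p$adopters, p$continuers, p$changers)
  if (is.null(cfg$exclude)) cfg$exclude <- "condom"
  cfg$exclude <- canonical_method_name(unlist(cfg$exclude))
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  structure(cfg, class = "run_config")
}

#' Execute a configured run
#'
#' Loads the inputs named by the config, runs the trend engine, and
#' writes `trend.csv`, `new_cpr_users.csv`, `summary.txt` and
#' `provenance.json` (input hashes and package version) into the output
#' directory.
#'
#' @param config A `run_config` (from [read_run_config()]) or a path to
#'   one.
#' @return The [run_trend()] result, invisibly.
#' @export
run_command <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  history <- read_service_history(config$history)
  assumptions <- read_assumption_set(config$assumptions)
  trend <- run_trend(history, assumptions, config$profile,
                     config$y_start, config$y_end, config$exclude)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_trend_csv(trend, file.path(out, "trend.csv"))
  utils::write.csv(trend$new_cpr_users, file.path(out, "new_cpr_users.csv"),
                   row.names = FALSE)
  summary_report(trend, file.path(out, "summary.txt"))
  prov <- list(
    package = "fpimpact",
    version = as.character(utils::packageVersion("fpimpact")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = list(
      history = unname(tools::md5sum(config$history)),
      assumptions = unname(tools::md5sum(config$assumptions))),
    y_start = config$y_start, y_end = config$y_end,
    exclude = config$exclude)
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(trend)
}
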