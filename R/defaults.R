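#' Read an assumption set from a config file
#'
#' The config (YAML or JSON, chosen by extension) names the demographic
#' series file, the life-table file and family, the median age of
#' sterilisation, the CPR basis, and one entry per method. Long-acting
#' methods give their CCR table either inline (`ccr:`) or as a CSV
#' (`ccr_file:`, columns `year_offset`, `ccr`); short-term methods give
#' `units_per_year`. All file paths are resolved relative to the config
#' file. Every invariant (monotone CCRs, positive WRA, ...) is enforced
#' at load time.
#'
#' @param path Path to the config file.
#' @return An [assumption_set()].
#' @export
read_assumption_set <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- read_config(path)
  dir <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(dir, p)

  d <- utils::read.csv(rel(cfg$demography$file), strip.white = TRUE)
  demo <- demographic_series(d$year, d$wra, d$prop_in_union, d$e0)

  lt_raw <- utils::read.csv(rel(cfg$life_table$file), strip.white = TRUE)
  fam <- cfg$life_table$family
  lt_rows <- lt_raw[lt_raw$family == fam, , drop = FALSE]
  if (!nrow(lt_rows))
    stop("life-table family '", fam, "' not found in ", cfg$life_table$file,
         "; available: ", paste(unique(lt_raw$family), collapse = ", "))
  lt <- life_table_family(fam, lt_rows[c("e0_level", "age_group_start", "p5x")])

  methods <- lapply(cfg$methods, function(m) {
    ccr <- m$ccr
    if (!is.null(m$ccr_file)) {
      tab <- utils::read.csv(rel(m$ccr_file), strip.white = TRUE)
      ccr <- tab$ccr[order(tab$year_offset)]
    }
    method_spec(m$name, m$category,
                max_duration = m$max_duration, ccr = unlist(ccr),
                units_per_year = m$units_per_year, cyp_factor = m$cyp_factor)
  })
  assumption_set(methods, demo, lt,
                 median_age_sterilisation = cfg$median_age_sterilisation,
                 cpr_basis = cfg$cpr_basis)
}

#' Write an assumption set to a config directory
#'
#' Inverse of [read_assumption_set()]: writes `<name>.yaml` plus the
#' demographic, life-table and per-method CCR CSVs into `dir`, so an
#' in-memory assumption set (e.g. a generated one) can be edited and
#' reloaded.
#'
#' @param assumptions An [assumption_set()].
#' @param dir Output directory (created if needed).
#' @param name Basename for the config file.
#' @return The config file path, invisibly.
#' @export
write_assumption_set <- function(assumptions, dir, name = "assumptions") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  demo_file <- paste0(name, "_demography.csv")
  utils::write.csv(as.data.frame(unclass(assumptions$demography)),
                   file.path(dir, demo_file), row.names = FALSE)
  lt_file <- paste0(name, "_life_table.csv")
  lt <- assumptions$life_table$levels
  lt$family <- assumptions$life_table$name
  utils::write.csv(lt[c("family", "e0_level", "age_group_start", "p5x")],
                   file.path(dir, lt_file), row.names = FALSE)
  methods <- lapply(assumptions$methods, function(m) {
    entry <- list(name = m$name, category = m$category)
    if (m$category == "long-acting") {
      ccr_file <- paste0(name, "_ccr_", m$name, ".csv")
      utils::write.csv(data.frame(year_offset = seq_along(m$ccr) - 1L,
                                  ccr = m$ccr),
                       file.path(dir, ccr_file), row.names = FALSE)
      entry$max_duration <- m$max_duration
      entry$ccr_file <- ccr_file
    }
    if (m$category == "short-term") entry$units_per_year <- m$units_per_year
    if (!is.null(m$cyp_factor)) entry$cyp_factor <- m$cyp_factor
    entry
  })
  cfg <- list(cpr_basis = assumptions$cpr_basis,
              median_age_sterilisation = assumptions$median_age_sterilisation,
              demography = list(file = demo_file),
              life_table = list(file = lt_file,
                                family = assumptions$life_table$name),
              methods = unname(methods))
  path <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Bundled default method portfolio
#'
#' The standard ten-method portfolio with editable default parameters:
#' five long-acting methods (10- and 5-year IUDs, 5-, 4- and 3-year
#' implants) with bundled CCR tables, two permanent methods (female and
#' male sterilisation), and three short-term methods (pill at 13 cycles
#' per covered year, injectable at 4 doses, condom at 120 units). The
#' bundled CCR tables are synthetic defaults constructed for this
#' package (plausible, monotone); programmes should replace them with
#' their nationally applicable continuation tables, which are revised
#' regularly. CYP factors are the conventional per-unit values (e.g. a
#' 10-year IUD is 4.6 CYPs, a pill cycle 1/15th).
#'
#' @return Named list of [method_spec()] objects.
#' @export
default_method_specs <- function() {
  default_assumption_set()$methods
}

#' Bundled default assumption set
#'
#' Loads the package's default config from `inst/extdata/defaults`: the
#' default method portfolio plus a synthetic demographic series and a
#' synthetic two-family life table, suitable for demonstrations and
#' tests. Real analyses should supply their country's demography, CCR
#' tables and assigned life-table family via [read_assumption_set()].
#'
#' @return An [assumption_set()].
#' @export
default_assumption_set <- function() {
  read_assumption_set(system.file("extdata", "defaults", "assumptions.yaml",
                                  package = "fpimpact", mustWork = TRUE))
}

# Parse YAML or JSON by extension.
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE,
                                              simplifyDataFrame = FALSE)
  else stop("config must be .yaml/.yml or .json, got: ", path)
}
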