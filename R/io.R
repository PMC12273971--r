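# CSV readers/writers for the input tables and YAML/JSON scenario configs.
# Dialect: comma-separated, UTF-8, header row required, period decimal
# separator. On disk the expenditure value column is named value_musd2018 to
# carry its units; in memory it is `value`.

read_table_checked <- function(path, what, col_types) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  x <- readr::read_csv(path, col_types = col_types, progress = FALSE)
  x
}

#' Read and write expenditure series
#'
#' `read_che()` loads a projected current health expenditure table from CSV
#' (columns `country`, `age_group`, `chapter`, `year`, `value_musd2018`) and
#' validates it; gaps in the year coverage of any (country, age group,
#' chapter) cell are rejected with the offending key named. `write_che()`
#' writes the same schema, so a write/read round trip reproduces the series.
#'
#' @param path Path to a CSV file.
#' @param years Optional integer vector of years the series must cover.
#' @return `read_che()` returns a validated [che_series()].
#' @export
read_che <- function(path, years = NULL) {
  x <- read_table_checked(path, "che", readr::cols(
    country = readr::col_character(),
    age_group = readr::col_integer(),
    chapter = readr::col_character(),
    year = readr::col_integer(),
    value_musd2018 = readr::col_double()
  ))
  if (!"value_musd2018" %in% names(x)) {
    stop("che file is missing column value_musd2018", call. = FALSE)
  }
  x <- dplyr::rename(x, value = "value_musd2018")
  che_series(x, years = years)
}

#' @rdname read_che
#' @param che A validated `che_series`.
#' @export
write_che <- function(che, path) {
  che <- validate_che(che)
  out <- dplyr::rename(che, value_musd2018 = "value")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write attributable-fraction series
#'
#' CSV schema: `country`, `age_group`, `condition`, `risk_factor`, `year`,
#' `fraction`. Validation enforces fractions in \[0, 1\] and zeros on
#' unlinked (risk factor, condition) pairs.
#'
#' @param path Path to a CSV file.
#' @param links Logical link matrix; defaults to [link_matrix()].
#' @return `read_paf()` returns a validated [paf_series()].
#' @export
read_paf <- function(path, links = link_matrix()) {
  x <- read_table_checked(path, "paf", readr::cols(
    country = readr::col_character(),
    age_group = readr::col_integer(),
    condition = readr::col_character(),
    risk_factor = readr::col_character(),
    year = readr::col_integer(),
    fraction = readr::col_double()
  ))
  paf_series(x, links = links)
}

#' @rdname read_paf
#' @param paf A validated `paf_series`.
#' @export
write_paf <- function(paf, path) {
  paf <- validate_paf(paf)
  readr::write_csv(paf, path, progress = FALSE)
  invisible(path)
}

#' Read and write DALY series
#'
#' CSV schema: `country`, `age_group`, `condition`, `year`, `dalys`.
#'
#' @param path Path to a CSV file.
#' @return `read_daly()` returns a validated [daly_series()].
#' @export
read_daly <- function(path) {
  x <- read_table_checked(path, "daly", readr::cols(
    country = readr::col_character(),
    age_group = readr::col_integer(),
    condition = readr::col_character(),
    year = readr::col_integer(),
    dalys = readr::col_double()
  ))
  daly_series(x)
}

#' @rdname read_daly
#' @param daly A validated `daly_series`.
#' @export
write_daly <- function(daly, path) {
  daly <- validate_daly(daly)
  readr::write_csv(daly, path, progress = FALSE)
  invisible(path)
}

#' Read and write the country register
#'
#' CSV schema: `code`, `name`, `region`, `expenditure_group`.
#'
#' @param path Path to a CSV file.
#' @return `read_countries()` returns a validated [cra_countries()].
#' @export
read_countries <- function(path) {
  x <- read_table_checked(path, "countries", readr::cols(
    code = readr::col_character(),
    name = readr::col_character(),
    region = readr::col_character(),
    expenditure_group = readr::col_integer()
  ))
  cra_countries(x)
}

#' @rdname read_countries
#' @param countries A validated `cra_countries` table.
#' @export
write_countries <- function(countries, path) {
  countries <- cra_countries(countries)
  readr::write_csv(countries, path, progress = FALSE)
  invisible(path)
}

#' Read a scenario configuration from YAML or JSON
#'
#' The file carries the keys of [cra_scenario()]: `reductions` (a mapping of
#' risk factor to fraction), `start_year`, `ramp_years`, `horizon_end`,
#' `discount_rate`, `base_year`. Missing keys take the scenario defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cra_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("scenario file not found: %s", path), call. = FALSE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  scenario_from_config(cfg)
}

scenario_from_config <- function(cfg) {
  if (is.null(cfg$reductions)) {
    stop("scenario config must contain a `reductions` mapping", call. = FALSE)
  }
  red <- unlist(cfg$reductions)
  args <- list(reductions = red)
  for (key in c("start_year", "ramp_years", "horizon_end", "discount_rate",
                "base_year")) {
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  }
  do.call(cra_scenario, args)
}
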