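# Baseline expenditure projection: the deterministic multiplicative
# recurrence used as the counterfactual when only a base-year expenditure
# snapshot (not a full projection) is available. Each cell grows from the
# previous year by three factors — population change, disease-prevalence
# change and a composite residual (technology, wages, coverage) — compounded
# annually:
#
#   CHE(t) = CHE(t-1) * (1 + pop) * (1 + prev) * (1 + residual)
#
# Chapter XXI (factors influencing health status) has no meaningful
# prevalence trend, so its prevalence factor is held flat at zero.

#' Growth components for the baseline projection
#'
#' Three per-annum growth-rate tables: `pop_change` by (country, age group,
#' year), `prev_change` by (country, chapter, age group, year) and
#' `residual_growth` by (country, year). All rates must exceed -1 so the
#' annual multipliers stay positive.
#'
#' @param pop_change Data frame with columns `country`, `age_group`, `year`,
#'   `rate`.
#' @param prev_change Data frame with columns `country`, `chapter`,
#'   `age_group`, `year`, `rate`.
#' @param residual_growth Data frame with columns `country`, `year`, `rate`.
#' @return A `growth_components` list.
#' @export
growth_components <- function(pop_change, prev_change, residual_growth) {
  chk <- function(x, cols, what) {
    missing <- setdiff(cols, names(x))
    if (length(missing) > 0) {
      stop(sprintf("%s is missing column(s): %s", what,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (any(x$rate <= -1)) {
      stop(sprintf("%s has rate <= -1 (multiplier would be nonpositive)",
                   what), call. = FALSE)
    }
    tibble::as_tibble(x[cols])
  }
  structure(
    list(
      pop_change = chk(pop_change, c("country", "age_group", "year", "rate"),
                       "pop_change"),
      prev_change = chk(prev_change,
                        c("country", "chapter", "age_group", "year", "rate"),
                        "prev_change"),
      residual_growth = chk(residual_growth, c("country", "year", "rate"),
                            "residual_growth")
    ),
    class = "growth_components"
  )
}

#' Project expenditure forward from a base-year snapshot
#'
#' Applies the annual multiplicative recurrence per (country, age group,
#' chapter) from the base year through `horizon_end`. Growth components
#' apply at year boundaries (discrete annual compounding). Chapter XXI's
#' prevalence factor is forced to zero regardless of the supplied table.
#'
#' @param base A [che_series()] restricted to a single base year, covering
#'   every (country, age group, chapter) to be projected.
#' @param growth A [growth_components()] object covering every projected
#'   cell-year; a missing component is an error naming the cell.
#' @param horizon_end Last projected year.
#' @return A validated [che_series()] spanning base year through
#'   `horizon_end`.
#' @export
#' @examples
#' base <- che_series(data.frame(country = "AA", age_group = 40,
#'                               chapter = "IX", year = 2020, value = 100))
#' g <- growth_components(
#'   data.frame(country = "AA", age_group = 40, year = 2021:2022, rate = 0.05),
#'   data.frame(country = "AA", chapter = "IX", age_group = 40,
#'              year = 2021:2022, rate = 0),
#'   data.frame(country = "AA", year = 2021:2022, rate = 0))
#' project_che(base, g, 2022)
project_che <- function(base, growth, horizon_end) {
  base <- validate_che(base)
  if (length(unique(base$year)) != 1) {
    stop("`base` must contain exactly one (base) year", call. = FALSE)
  }
  base_year <- base$year[1]
  if (horizon_end < base_year) {
    stop("horizon_end must be >= the base year", call. = FALSE)
  }
  if (horizon_end == base_year) return(base)
  years <- seq.int(base_year + 1L, horizon_end)

  grid <- tidyr::expand_grid(
    dplyr::distinct(base, .data$country, .data$age_group, .data$chapter),
    year = years
  )
  grid <- grid |>
    dplyr::left_join(dplyr::rename(growth$pop_change, pop = "rate"),
                     by = c("country", "age_group", "year")) |>
    dplyr::left_join(dplyr::rename(growth$prev_change, prev = "rate"),
                     by = c("country", "chapter", "age_group", "year")) |>
    dplyr::left_join(dplyr::rename(growth$residual_growth, res = "rate"),
                     by = c("country", "year"))
  grid$prev[grid$chapter == "XXI"] <- 0
  for (comp in c("pop", "prev", "res")) {
    miss <- which(is.na(grid[[comp]]))
    if (length(miss) > 0) {
      i <- miss[1]
      stop(sprintf(
        "missing %s rate for (%s, age %s, chapter %s, %d)",
        switch(comp, pop = "pop_change", prev = "prev_change",
               res = "residual_growth"),
        grid$country[i], grid$age_group[i], grid$chapter[i], grid$year[i]),
        call. = FALSE)
    }
  }
  grid$mult <- (1 + grid$pop) * (1 + grid$prev) * (1 + grid$res)
  grid <- grid |>
    dplyr::arrange(.data$country, .data$age_group, .data$chapter,
                   .data$year) |>
    dplyr::group_by(.data$country, .data$age_group, .data$chapter) |>
    dplyr::mutate(cum = cumprod(.data$mult)) |>
    dplyr::ungroup()
  grid <- dplyr::left_join(
    grid,
    dplyr::select(base, "country", "age_group", "chapter", base_value = "value"),
    by = c("country", "age_group", "chapter"))
  grid$value <- grid$base_value * grid$cum
  out <- dplyr::bind_rows(
    base,
    dplyr::select(grid, "country", "age_group", "chapter", "year", "value"))
  che_series(out)
}

#' Read and write growth-component tables
#'
#' `read_growth()` expects `pop_growth.csv`, `prev_growth.csv` and
#' `residual_growth.csv` in `dir`, with the column schemas of
#' [growth_components()]; `write_growth()` emits them.
#'
#' @param dir Directory containing (or to receive) the three CSVs.
#' @return `read_growth()` returns a `growth_components` object.
#' @export
read_growth <- function(dir) {
  rd <- function(name, col_types) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      stop(sprintf("growth file not found: %s", path), call. = FALSE)
    }
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  }
  growth_components(
    pop_change = rd("pop_growth.csv", "ciid"),
    prev_change = rd("prev_growth.csv", "cciid"),
    residual_growth = rd("residual_growth.csv", "cid")
  )
}

#' @rdname read_growth
#' @param growth A `growth_components` object.
#' @export
write_growth <- function(growth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(growth$pop_change, file.path(dir, "pop_growth.csv"),
                   progress = FALSE)
  readr::write_csv(growth$prev_change, file.path(dir, "prev_growth.csv"),
                   progress = FALSE)
  readr::write_csv(growth$residual_growth,
                   file.path(dir, "residual_growth.csv"), progress = FALSE)
  invisible(dir)
}
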