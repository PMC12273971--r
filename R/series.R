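# Validated tabular series underlying the CRA: expenditure, attributable
# fraction and DALY tables, plus the country register. Each is a tibble with
# a class tag; validators enforce the keying and range invariants once at
# construction so the engine can assume them.

series_cols <- list(
  che_series  = c("country", "age_group", "chapter", "year", "value"),
  paf_series  = c("country", "age_group", "condition", "risk_factor", "year", "fraction"),
  daly_series = c("country", "age_group", "condition", "year", "dalys"),
  cra_countries = c("code", "name", "region", "expenditure_group")
)

check_columns <- function(x, what) {
  need <- series_cols[[what]]
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

new_series <- function(x, class) {
  x <- tibble::as_tibble(x)
  class(x) <- c(class, class(tibble::tibble()))
  x
}

#' Projected current health expenditure series
#'
#' Expenditure in million 2018 US$ keyed by (country, age group, ICD-10
#' chapter, year). Values must be nonnegative and every (country, age group,
#' chapter) cell must be present for every year it spans: the series is the
#' counterfactual a scenario is evaluated against, so year gaps are rejected
#' at construction.
#'
#' @param x A data frame with columns `country`, `age_group`, `chapter`,
#'   `year`, `value`.
#' @param years Optional integer vector of years the series must cover;
#'   defaults to the full range of years present.
#' @return A validated `che_series` tibble.
#' @export
che_series <- function(x, years = NULL) {
  check_columns(x, "che_series")
  x <- new_series(x[series_cols$che_series], "che_series")
  validate_che(x, years = years)
}

#' @rdname che_series
#' @param che A `che_series` (or compatible data frame) to validate.
#' @export
validate_che <- function(che, years = NULL) {
  check_columns(che, "che_series")
  if (anyNA(che$value)) {
    stop("che_series contains missing values", call. = FALSE)
  }
  bad <- which(che$value < 0)
  if (length(bad) > 0) {
    i <- bad[1]
    stop(sprintf(
      "che_series has negative value %g at (%s, age %s, chapter %s, %d)",
      che$value[i], che$country[i], che$age_group[i], che$chapter[i],
      che$year[i]), call. = FALSE)
  }
  dup <- anyDuplicated(che[c("country", "age_group", "chapter", "year")])
  if (dup > 0) {
    stop(sprintf("che_series has a duplicated key at row %d", dup),
         call. = FALSE)
  }
  if (is.null(years)) years <- seq.int(min(che$year), max(che$year))
  counts <- dplyr::count(che, .data$country, .data$age_group, .data$chapter)
  gaps <- counts[counts$n != length(years), , drop = FALSE]
  if (nrow(gaps) > 0) {
    key <- gaps[1, ]
    have <- che$year[che$country == key$country &
                       che$age_group == key$age_group &
                       che$chapter == key$chapter]
    miss <- setdiff(years, have)
    stop(sprintf(
      "che_series is missing year(s) %s for (%s, age %s, chapter %s)",
      paste(miss, collapse = ", "), key$country, key$age_group, key$chapter),
      call. = FALSE)
  }
  che
}

#' Population attributable fraction series
#'
#' The share of a condition's DALYs attributable to a risk factor, keyed by
#' (country, age group, condition, risk factor, year). Fractions lie in
#' \[0, 1\] and must be exactly zero wherever the risk-factor-to-condition
#' link is absent (see [link_matrix()]).
#'
#' @param x A data frame with columns `country`, `age_group`, `condition`,
#'   `risk_factor`, `year`, `fraction`.
#' @param links Logical link matrix; defaults to [link_matrix()].
#' @return A validated `paf_series` tibble.
#' @export
paf_series <- function(x, links = link_matrix()) {
  check_columns(x, "paf_series")
  x <- new_series(x[series_cols$paf_series], "paf_series")
  validate_paf(x, links)
}

#' @rdname paf_series
#' @param paf A `paf_series` (or compatible data frame) to validate.
#' @export
validate_paf <- function(paf, links = link_matrix()) {
  check_columns(paf, "paf_series")
  if (anyNA(paf$fraction)) {
    stop("paf_series contains missing fractions", call. = FALSE)
  }
  bad <- which(paf$fraction < 0 | paf$fraction > 1)
  if (length(bad) > 0) {
    i <- bad[1]
    stop(sprintf(
      "paf_series fraction %g outside [0, 1] at (%s, age %s, %s, %s, %d)",
      paf$fraction[i], paf$country[i], paf$age_group[i], paf$condition[i],
      paf$risk_factor[i], paf$year[i]), call. = FALSE)
  }
  unknown_rf <- setdiff(unique(paf$risk_factor), rownames(links))
  if (length(unknown_rf) > 0) {
    stop("unknown risk factor(s): ", paste(unknown_rf, collapse = ", "),
         call. = FALSE)
  }
  unknown_k <- setdiff(unique(paf$condition), colnames(links))
  if (length(unknown_k) > 0) {
    stop("unknown condition(s): ", paste(unknown_k, collapse = ", "),
         call. = FALSE)
  }
  linked <- links[cbind(paf$risk_factor, paf$condition)]
  off <- which(!linked & paf$fraction != 0)
  if (length(off) > 0) {
    i <- off[1]
    stop(sprintf(
      "paf_series has nonzero fraction %g on unlinked pair (%s -> %s)",
      paf$fraction[i], paf$risk_factor[i], paf$condition[i]), call. = FALSE)
  }
  paf
}

#' DALY series
#'
#' Total disability-adjusted life years keyed by (country, age group,
#' condition, year). Values must be nonnegative.
#'
#' @param x A data frame with columns `country`, `age_group`, `condition`,
#'   `year`, `dalys`.
#' @return A validated `daly_series` tibble.
#' @export
daly_series <- function(x) {
  check_columns(x, "daly_series")
  x <- new_series(x[series_cols$daly_series], "daly_series")
  validate_daly(x)
}

#' @rdname daly_series
#' @param daly A `daly_series` (or compatible data frame) to validate.
#' @export
validate_daly <- function(daly) {
  check_columns(daly, "daly_series")
  if (anyNA(daly$dalys)) {
    stop("daly_series contains missing values", call. = FALSE)
  }
  bad <- which(daly$dalys < 0)
  if (length(bad) > 0) {
    i <- bad[1]
    stop(sprintf(
      "daly_series has negative value %g at (%s, age %s, %s, %d)",
      daly$dalys[i], daly$country[i], daly$age_group[i], daly$condition[i],
      daly$year[i]), call. = FALSE)
  }
  daly
}

#' Country register
#'
#' One row per country: short code, display name, region (`latin_america` or
#' `caribbean`) and expenditure group (1-4, countries grouped by 2015-2019
#' average per-capita health expenditure).
#'
#' @param x A data frame with columns `code`, `name`, `region`,
#'   `expenditure_group`.
#' @return A validated `cra_countries` tibble.
#' @export
cra_countries <- function(x) {
  check_columns(x, "cra_countries")
  x <- new_series(x[series_cols$cra_countries], "cra_countries")
  bad_region <- setdiff(unique(x$region), c("latin_america", "caribbean"))
  if (length(bad_region) > 0) {
    stop("region must be 'latin_america' or 'caribbean'; got: ",
         paste(bad_region, collapse = ", "), call. = FALSE)
  }
  if (!all(x$expenditure_group %in% 1:4)) {
    stop("expenditure_group must be an integer in 1..4", call. = FALSE)
  }
  if (anyDuplicated(x$code) > 0) {
    stop("country codes must be unique", call. = FALSE)
  }
  x
}

#' Policy scenario
#'
#' A deterministic prevalence-reduction scenario: the fractional reduction in
#' each risk factor's prevalence, the year the policy starts, the length of
#' the linear phase-in (a risk-factor change translates into condition
#' prevalence over ten years by default), the end of the accounting horizon
#' and the discount specification.
#'
#' @param reductions Named numeric vector mapping risk factors to reduction
#'   fractions in \[0, 1\] (e.g. `c(tobacco = 0.10)`). Risk factors not named
#'   get reduction 0. Negative values (prevalence increases) are permitted
#'   and yield negative savings.
#' @param start_year Calendar year the policy starts (default 2020); the
#'   phase-in factor is 0 in this year.
#' @param ramp_years Length of the linear phase-in in years (default 10);
#'   full effect from `start_year + ramp_years` onwards.
#' @param horizon_end Last year of the accounting horizon (default 2050).
#' @param discount_rate Per-annum discount rate (default 0.03).
#' @param base_year Year discounting is anchored to; defaults to
#'   `start_year`.
#' @param allow_negative Permit negative reductions (default `TRUE`).
#' @return A `cra_scenario` list.
#' @export
#' @examples
#' cra_scenario(c(tobacco = 0.10, alcohol = 0.10))
cra_scenario <- function(reductions,
                         start_year = 2020L,
                         ramp_years = 10L,
                         horizon_end = 2050L,
                         discount_rate = 0.03,
                         base_year = start_year,
                         allow_negative = TRUE) {
  if (is.null(names(reductions)) || any(!nzchar(names(reductions)))) {
    stop("`reductions` must be a named numeric vector", call. = FALSE)
  }
  unknown <- setdiff(names(reductions), risk_factors())
  if (length(unknown) > 0) {
    stop("unknown risk factor(s) in reductions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(reductions > 1)) {
    stop("reductions cannot exceed 1 (a 100% prevalence reduction)",
         call. = FALSE)
  }
  if (!allow_negative && any(reductions < 0)) {
    stop("reductions must lie in [0, 1]", call. = FALSE)
  }
  if (ramp_years < 0) stop("ramp_years must be >= 0", call. = FALSE)
  if (horizon_end < start_year) {
    stop("horizon_end must be >= start_year", call. = FALSE)
  }
  if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  full <- stats::setNames(numeric(length(risk_factors())), risk_factors())
  full[names(reductions)] <- reductions
  structure(
    list(
      reductions = full,
      start_year = as.integer(start_year),
      ramp_years = as.integer(ramp_years),
      horizon_end = as.integer(horizon_end),
      discount_rate = discount_rate,
      base_year = as.integer(base_year)
    ),
    class = "cra_scenario"
  )
}

#' @export
print.cra_scenario <- function(x, ...) {
  nz <- x$reductions[x$reductions != 0]
  cat("<cra_scenario>\n")
  cat("  reductions:",
      if (length(nz) == 0) "(none)" else
        paste(sprintf("%s %g%%", names(nz), 100 * nz), collapse = ", "),
      "\n")
  cat(sprintf("  horizon: %d-%d (phase-in %d y from %d)\n",
              x$start_year, x$horizon_end, x$ramp_years, x$start_year))
  cat(sprintf("  discounting: %g%%/y from %d\n",
              100 * x$discount_rate, x$base_year))
  invisible(x)
}
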