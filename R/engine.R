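# Policy-impact engine. The annual impact for country i, age group j,
# condition k, risk factor p and year t is the product
#
#   CHE(i, j, chapter(k), t) * share(k) * reduction(p) * PAF(i, j, k, p, t)
#
# phased in linearly over `ramp_years` from the scenario start. All factors
# are evaluated at the impact year; the model is deliberately linear in the
# reduction and additive across risk factors (no interaction term), which the
# invariants and tests rely on.

#' Linear phase-in factor
#'
#' A prevalence change translates into condition prevalence over a multi-year
#' lag: the factor is 0 at `start_year`, rises linearly and reaches 1 at
#' `start_year + ramp_years`, remaining 1 thereafter. A zero-length ramp
#' jumps straight to full effect the year after start.
#'
#' @param year Calendar year(s); vectorised.
#' @param start_year Year the policy starts.
#' @param ramp_years Length of the phase-in in years.
#' @return Fraction(s) in \[0, 1\].
#' @export
#' @examples
#' ramp_factor(2020:2032, start_year = 2020, ramp_years = 10)
ramp_factor <- function(year, start_year, ramp_years = 10L) {
  if (ramp_years < 0) stop("ramp_years must be >= 0", call. = FALSE)
  if (ramp_years == 0) {
    return(as.numeric(year > start_year))
  }
  pmin(1, pmax(0, (year - start_year) / ramp_years))
}

#' Present-value discount factor
#'
#' End-of-year convention: the factor for `year` is
#' `(1 + rate)^-(year - base_year)`, so the base year itself is undiscounted.
#'
#' @param year Calendar year(s) at or after `base_year`; vectorised.
#' @param rate Per-annum discount rate (>= 0).
#' @param base_year Year discounting is anchored to.
#' @return Fraction(s) in (0, 1].
#' @export
#' @examples
#' discount_factor(2022, rate = 0.03, base_year = 2020) # 1 / 1.0609
discount_factor <- function(year, rate = 0.03, base_year) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (any(year < base_year)) {
    stop("cannot discount a year before base_year", call. = FALSE)
  }
  (1 + rate)^(-(year - base_year))
}

# Join CHE to conditions/PAF and compute the per-(country, rf, condition,
# year) undiscounted impact, summed over age groups. Shared by the annual
# and full-horizon entry points.
impact_core <- function(che, conditions_tbl, paf, scenario, years) {
  missing_ch <- setdiff(conditions_tbl$chapter, unique(che$chapter))
  if (length(missing_ch) > 0) {
    k <- conditions_tbl$condition[match(missing_ch, conditions_tbl$chapter)]
    stop(sprintf(
      "chapter(s) %s (condition %s) absent from the expenditure series",
      paste(missing_ch, collapse = ", "), paste(k, collapse = ", ")),
      call. = FALSE)
  }
  red <- tibble::tibble(
    risk_factor = names(scenario$reductions),
    reduction = unname(scenario$reductions)
  )
  che_y <- dplyr::filter(che, .data$year %in% years)
  paf_y <- dplyr::filter(paf, .data$year %in% years)
  cells <- che_y |>
    dplyr::inner_join(conditions_tbl, by = "chapter",
                      relationship = "many-to-many") |>
    dplyr::inner_join(paf_y,
                      by = c("country", "age_group", "condition", "year")) |>
    dplyr::inner_join(red, by = "risk_factor")
  ramp <- ramp_factor(cells$year, scenario$start_year, scenario$ramp_years)
  cells$impact <- cells$value * cells$share * cells$reduction *
    cells$fraction * ramp
  out <- cells |>
    dplyr::group_by(.data$country, .data$risk_factor, .data$condition,
                    .data$year) |>
    dplyr::summarise(undiscounted = sum(.data$impact), .groups = "drop")
  # carry explicit zeros for unlinked/absent pairs so the impact table is a
  # complete (country, risk_factor, condition, year) grid
  grid <- tidyr::expand_grid(
    country = unique(che_y$country),
    risk_factor = red$risk_factor,
    condition = conditions_tbl$condition,
    year = years
  )
  out <- dplyr::left_join(grid, out,
                          by = c("country", "risk_factor", "condition", "year"))
  out$undiscounted[is.na(out$undiscounted)] <- 0
  out
}

#' Annual policy impact
#'
#' The expenditure impact of a scenario in a single year, summed over age
#' groups, per (country, risk factor, condition). Undiscounted.
#'
#' @param che A validated [che_series()].
#' @param conditions_tbl Condition/chapter/share table,
#'   [default_condition_table()] by default.
#' @param paf A validated [paf_series()].
#' @param scenario A [cra_scenario()].
#' @param year The impact year.
#' @return A tibble with columns `country`, `risk_factor`, `condition`,
#'   `year`, `undiscounted` (million 2018 US$).
#' @export
annual_policy_impact <- function(che, conditions_tbl = default_condition_table(),
                                 paf, scenario, year) {
  impact_core(che, conditions_tbl, paf, scenario, years = year)
}

#' Run a scenario over the full horizon
#'
#' Computes the annual policy impact for every year from the scenario start
#' through `horizon_end`, with a discounted twin of each cell
#' (`discounted = undiscounted * discount_factor(year)`).
#'
#' @inheritParams annual_policy_impact
#' @return An `impact_table` tibble keyed by (country, risk_factor,
#'   condition, year) with columns `undiscounted` and `discounted`, both in
#'   million 2018 US$.
#' @export
#' @examples
#' inp <- generate_inputs(generator_config(seed = 1, n_latin = 2, n_carib = 1))
#' imp <- run_scenario(inp$che, default_condition_table(), inp$paf,
#'                     cra_scenario(c(tobacco = 0.10)))
#' head(imp)
run_scenario <- function(che, conditions_tbl = default_condition_table(),
                         paf, scenario) {
  years <- seq.int(scenario$start_year, scenario$horizon_end)
  out <- impact_core(che, conditions_tbl, paf, scenario, years = years)
  out$discounted <- out$undiscounted *
    discount_factor(out$year, scenario$discount_rate, scenario$base_year)
  class(out) <- c("impact_table", class(out))
  out
}

#' Cumulative discounted savings
#'
#' Sums the discounted impact over the horizon per (country, risk factor) and
#' expresses it as a percentage of the discounted cumulative base-case
#' expenditure over all chapters (the same discounting applied to numerator
#' and denominator keeps the percentage unit-free and invariant to a common
#' currency rescaling).
#'
#' @param impact An `impact_table` from [run_scenario()].
#' @param che The base-case [che_series()] the scenario was run against.
#' @param scenario The [cra_scenario()] used (supplies the discount spec).
#' @param countries Optional [cra_countries()] register; when supplied,
#'   region subtotals (`All Latin American countries`, `All Caribbean
#'   countries`) and a grand total (`All countries`) are appended, summed
#'   before any rounding.
#' @param discount_denominator Discount the base-case denominator as well
#'   (default `TRUE`).
#' @return A tibble with columns `country`, `risk_factor`, `savings`
#'   (discounted cumulative, million 2018 US$), `base_che` (the denominator)
#'   and `percent`.
#' @export
cumulative_savings <- function(impact, che, scenario, countries = NULL,
                               discount_denominator = TRUE) {
  years <- sort(unique(impact$year))
  if (length(years) == 0) stop("impact table has an empty horizon",
                               call. = FALSE)
  per_cell <- impact |>
    dplyr::group_by(.data$country, .data$risk_factor) |>
    dplyr::summarise(savings = sum(.data$discounted), .groups = "drop")
  base <- dplyr::filter(che, .data$year %in% years)
  dfac <- if (discount_denominator) {
    discount_factor(base$year, scenario$discount_rate, scenario$base_year)
  } else 1
  denom <- base |>
    dplyr::mutate(pv = .data$value * dfac) |>
    dplyr::group_by(.data$country) |>
    dplyr::summarise(base_che = sum(.data$pv), .groups = "drop")
  out <- dplyr::left_join(per_cell, denom, by = "country")
  out$percent <- 100 * out$savings / out$base_che
  if (!is.null(countries)) {
    out <- append_totals(out, countries)
  }
  out
}

append_totals <- function(savings, countries) {
  regions <- tibble::tibble(
    country = countries$code,
    region = countries$region
  )
  joined <- dplyr::inner_join(savings, regions, by = "country")
  region_rows <- joined |>
    dplyr::group_by(.data$region, .data$risk_factor) |>
    dplyr::summarise(savings = sum(.data$savings),
                     base_che = sum(unique(.data$base_che)),
                     .groups = "drop")
  # base_che is per country, repeated across risk factors: recompute cleanly
  denom_by_country <- savings |>
    dplyr::distinct(.data$country, .data$base_che) |>
    dplyr::inner_join(regions, by = "country")
  region_denom <- denom_by_country |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(base_che = sum(.data$base_che), .groups = "drop")
  region_rows <- joined |>
    dplyr::group_by(.data$region, .data$risk_factor) |>
    dplyr::summarise(savings = sum(.data$savings), .groups = "drop") |>
    dplyr::inner_join(region_denom, by = "region") |>
    dplyr::mutate(
      country = ifelse(.data$region == "latin_america",
                       "All Latin American countries",
                       "All Caribbean countries"),
      percent = 100 * .data$savings / .data$base_che
    ) |>
    dplyr::select("country", "risk_factor", "savings", "base_che", "percent")
  grand <- joined |>
    dplyr::group_by(.data$risk_factor) |>
    dplyr::summarise(savings = sum(.data$savings), .groups = "drop") |>
    dplyr::mutate(
      country = "All countries",
      base_che = sum(denom_by_country$base_che),
      percent = 100 * .data$savings / .data$base_che
    ) |>
    dplyr::select("country", "risk_factor", "savings", "base_che", "percent")
  dplyr::bind_rows(savings, region_rows, grand)
}

#' Percent DALY reduction by condition and risk factor
#'
#' For each reduction level s, condition and risk factor: within each
#' country, the DALY-weighted mean attributable fraction over age groups
#' (evaluated at a full-phase-in year), times s, times 100; then averaged
#' (unweighted by default) across countries. Under attributable fractions
#' that are uniform across countries and ages this collapses to the exact
#' product `s * PAF * 100`.
#'
#' @param paf A validated [paf_series()].
#' @param daly A validated [daly_series()] supplying the within-country age
#'   weights.
#' @param reduction_levels Reduction fractions to tabulate (default 5%, 10%,
#'   25%).
#' @param year Year at which fractions and weights are evaluated; defaults to
#'   the last year common to both series (with time-constant fractions the
#'   choice is immaterial).
#' @param country_weighting `"unweighted"` (default) averages countries
#'   equally; `"daly_weighted"` weights them by total DALYs.
#' @return A `daly_summary` tibble with columns `condition`, `risk_factor`,
#'   `level`, `percent`. Unlinked pairs carry `NA` percent. Countries with
#'   zero total DALYs for a condition are excluded from that condition's
#'   average with a warning.
#' @export
daly_reduction <- function(paf, daly,
                           reduction_levels = c(0.05, 0.10, 0.25),
                           year = NULL,
                           country_weighting = c("unweighted",
                                                 "daly_weighted")) {
  country_weighting <- match.arg(country_weighting)
  if (any(reduction_levels < 0)) {
    stop("reduction levels must be >= 0", call. = FALSE)
  }
  if (is.null(year)) {
    year <- min(max(paf$year), max(daly$year))
  }
  paf_y <- dplyr::filter(paf, .data$year == !!year)
  daly_y <- dplyr::filter(daly, .data$year == !!year)
  if (nrow(paf_y) == 0 || nrow(daly_y) == 0) {
    stop(sprintf("no PAF/DALY rows at year %d", year), call. = FALSE)
  }
  cells <- dplyr::inner_join(
    paf_y, daly_y, by = c("country", "age_group", "condition", "year"))
  totals <- cells |>
    dplyr::distinct(.data$country, .data$age_group, .data$condition,
                    .data$dalys) |>
    dplyr::group_by(.data$country, .data$condition) |>
    dplyr::summarise(total = sum(.data$dalys), .groups = "drop")
  zero <- dplyr::filter(totals, .data$total == 0)
  if (nrow(zero) > 0) {
    warning(sprintf(
      "excluding %d (country, condition) pair(s) with zero total DALYs: %s",
      nrow(zero),
      paste(utils::head(paste0(zero$country, "/", zero$condition), 5),
            collapse = ", ")), call. = FALSE)
  }
  wbar <- cells |>
    dplyr::inner_join(dplyr::filter(totals, .data$total > 0),
                      by = c("country", "condition")) |>
    dplyr::group_by(.data$country, .data$condition, .data$risk_factor) |>
    dplyr::summarise(
      paf_bar = sum(.data$fraction * .data$dalys) / .data$total[1],
      total = .data$total[1],
      .groups = "drop")
  across <- wbar |>
    dplyr::group_by(.data$condition, .data$risk_factor) |>
    dplyr::summarise(
      paf_bar = if (country_weighting == "unweighted") {
        mean(.data$paf_bar)
      } else {
        sum(.data$paf_bar * .data$total) / sum(.data$total)
      },
      .groups = "drop")
  out <- tidyr::expand_grid(
    condition = conditions(),
    risk_factor = risk_factors(),
    level = reduction_levels
  ) |>
    dplyr::left_join(across, by = c("condition", "risk_factor")) |>
    dplyr::left_join(link_pairs(), by = c("risk_factor", "condition"))
  out$percent <- ifelse(out$linked, 100 * out$level *
                          dplyr::coalesce(out$paf_bar, 0), NA_real_)
  out <- dplyr::select(out, "condition", "risk_factor", "level", "percent")
  class(out) <- c("daly_summary", class(out))
  out
}
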