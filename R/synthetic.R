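# Synthetic input generator. Emulates the joint structure of the inputs the
# CRA consumes — a burden-of-disease style PAF/DALY extract and a
# chapter-by-age expenditure projection — for 24 Latin American and
# Caribbean countries, so the full pipeline runs and is tested without any
# external download. Magnitudes are calibrated to the published structure
# (country expenditure groups, attributable-fraction levels back-solved from
# the reported DALY reductions), not to any real country.

#' Default attributable-fraction ranges
#'
#' Per linked (risk factor, condition) pair, the \[lo, hi\] interval country
#' level fractions are drawn from. Centres are the regional mean fractions
#' implied by the reported percent DALY reductions (percent / (100 * s));
#' widths are +/-10% relative, clipped to \[0, 1\]. Diabetes is fully
#' attributable to high blood glucose by definition, so that pair is fixed
#' at 1.
#'
#' @return A tibble with columns `risk_factor`, `condition`, `lo`, `hi`.
#' @export
default_paf_ranges <- function() {
  centre <- tibble::tribble(
    ~risk_factor,   ~condition,    ~mid,
    "tobacco",      "cvd",         0.147,
    "tobacco",      "cancer",      0.157,
    "tobacco",      "copd",        0.458,
    "tobacco",      "diabetes_t2", 0.129,
    "high_sbp",     "cvd",         0.5232,
    "high_sbp",     "ckd",         0.564,
    "high_glucose", "cvd",         0.230,
    "high_glucose", "cancer",      0.039,
    "high_glucose", "diabetes_t2", 1.000,
    "high_glucose", "ckd",         0.310,
    "alcohol",      "cvd",         0.017,
    "alcohol",      "cancer",      0.041
  )
  dplyr::mutate(centre,
                lo = ifelse(.data$mid == 1, 1, pmax(0, .data$mid * 0.9)),
                hi = pmin(1, .data$mid * 1.1)) |>
    dplyr::select("risk_factor", "condition", "lo", "hi")
}

#' Generator configuration
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_latin Number of Latin American countries (default 16).
#' @param n_carib Number of Caribbean countries (default 8).
#' @param years Year range of the generated series (default 2020-2050).
#' @param che_growth_mean,che_growth_sd Mean and spread of the per-annum
#'   expenditure growth rate drawn per (country, chapter).
#' @param paf_ranges Tibble of draw ranges per linked pair; defaults to
#'   [default_paf_ranges()]. Pairs absent from the table get fraction 0.
#' @param daly_scale Magnitude parameter: roughly the total DALYs across the
#'   five conditions for a mid-sized country-year.
#' @param paf_drift Per-annum relative drift of fractions (default 0:
#'   time-constant fractions, the least-assumption default).
#' @param paf_age_gradient Relative spread of a mild monotone-in-age gradient
#'   on fractions (default 0: off).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_latin = 16L,
                             n_carib = 8L,
                             years = 2020:2050,
                             che_growth_mean = 0.04,
                             che_growth_sd = 0.01,
                             paf_ranges = default_paf_ranges(),
                             daly_scale = 2e5,
                             paf_drift = 0,
                             paf_age_gradient = 0) {
  if (n_latin + n_carib < 1) stop("need at least one country", call. = FALSE)
  if (any(paf_ranges$lo < 0 | paf_ranges$hi > 1 |
            paf_ranges$lo > paf_ranges$hi)) {
    stop("paf_ranges must satisfy 0 <= lo <= hi <= 1", call. = FALSE)
  }
  links <- link_matrix()
  off <- !links[cbind(paf_ranges$risk_factor, paf_ranges$condition)]
  if (any(off)) {
    i <- which(off)[1]
    stop(sprintf("paf_ranges contains unlinked pair (%s -> %s)",
                 paf_ranges$risk_factor[i], paf_ranges$condition[i]),
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_latin = as.integer(n_latin),
         n_carib = as.integer(n_carib), years = as.integer(years),
         che_growth_mean = che_growth_mean, che_growth_sd = che_growth_sd,
         paf_ranges = paf_ranges, daly_scale = daly_scale,
         paf_drift = paf_drift, paf_age_gradient = paf_age_gradient),
    class = "generator_config"
  )
}

# One named stream per (dataset, country): each country's draws come from a
# seed derived from the master seed, the dataset name and the country code
# itself (not its position), so adding or removing a country never perturbs
# other countries' draws.
stream_seed <- function(seed, dataset, code) {
  dataset_id <- match(dataset, c("countries", "che", "paf", "daly"))
  h <- 0
  for (b in utf8ToInt(code)) h <- (h * 131 + b) %% 2147483399
  as.integer((abs(seed) * 48271 + dataset_id * 69621 + h * 16807) %%
               2147483399)
}

synth_countries <- function(config) {
  n <- config$n_latin + config$n_carib
  code <- c(sprintf("LA%02d", seq_len(config$n_latin)),
            sprintf("CB%02d", seq_len(config$n_carib)))
  region <- c(rep("latin_america", config$n_latin),
              rep("caribbean", config$n_carib))
  # expenditure groups 1 (highest per-capita spending) to 4, cycled within
  # region so every group is represented on both sides
  grp <- c(rep_len(1:4, config$n_latin), rep_len(1:4, config$n_carib))
  cra_countries(tibble::tibble(
    code = code,
    name = paste("Country", code),
    region = region,
    expenditure_group = grp
  ))
}

# Chapter weight profile: the five condition-bearing chapters get realistic
# double-digit-to-mid-single-digit shares of national expenditure; the
# remaining 16 chapters share the rest evenly before per-country noise.
chapter_base_weights <- function() {
  ch <- icd_chapters()
  w <- stats::setNames(rep(0.58 / 16, length(ch)), ch)
  w["II"] <- 0.10; w["IV"] <- 0.06; w["IX"] <- 0.13
  w["X"] <- 0.08; w["XIV"] <- 0.05
  w / sum(w)
}

# Expenditure rises steeply with age, as in observed age-expenditure
# profiles.
age_weights <- function() {
  a <- age_groups()
  w <- 0.4 + 2.2 * (a / 85)^1.6
  w / sum(w)
}

#' Generate a full synthetic input set
#'
#' Deterministic for a fixed seed. Expenditure is strictly positive with
#' smooth compound growth per (country, chapter); attributable fractions are
#' drawn per country inside the configured ranges (time-constant unless a
#' drift is configured, uniform over age unless an age gradient is
#' configured) and exactly zero off the link matrix; DALYs are positive with
#' heavier burdens at older ages. Country expenditure magnitudes are drawn
#' per expenditure group so the four-group structure is represented.
#'
#' @param config A [generator_config()].
#' @return A list with elements `che` ([che_series()]), `paf`
#'   ([paf_series()]), `daly` ([daly_series()]) and `countries`
#'   ([cra_countries()]).
#' @export
#' @examples
#' inp <- generate_inputs(generator_config(seed = 7, n_latin = 2, n_carib = 1))
#' lapply(inp, nrow)
generate_inputs <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop("`config` must come from generator_config()", call. = FALSE)
  }
  countries <- synth_countries(config)
  years <- config$years
  ages <- age_groups()
  chapters <- icd_chapters()
  base_w <- chapter_base_weights()
  age_w <- age_weights()
  # annual expenditure scale (million US$) per expenditure group
  group_scale <- c(60000, 25000, 10000, 4000)

  che_parts <- vector("list", nrow(countries))
  paf_parts <- vector("list", nrow(countries))
  daly_parts <- vector("list", nrow(countries))
  ranges <- config$paf_ranges
  cond_w <- stats::setNames(c(0.25, 0.15, 0.35, 0.15, 0.10), conditions())

  for (i in seq_len(nrow(countries))) {
    cc <- countries$code[i]
    grp <- countries$expenditure_group[i]

    set.seed(stream_seed(config$seed, "che", cc))
    scale_i <- group_scale[grp] * exp(stats::rnorm(1, 0, 0.35))
    w <- base_w * exp(stats::rnorm(length(chapters), 0, 0.15))
    w <- w / sum(w)
    growth <- stats::rnorm(length(chapters), config$che_growth_mean,
                           config$che_growth_sd)
    grid <- tidyr::expand_grid(age_group = ages, chapter = chapters,
                               year = years)
    grid$country <- cc
    gidx <- match(grid$chapter, chapters)
    grid$value <- scale_i * w[gidx] * age_w[match(grid$age_group, ages)] *
      (1 + growth[gidx])^(grid$year - years[1])
    che_parts[[i]] <- grid[c("country", "age_group", "chapter", "year",
                             "value")]

    set.seed(stream_seed(config$seed, "paf", cc))
    u <- stats::runif(nrow(ranges), ranges$lo, ranges$hi)
    pgrid <- tidyr::expand_grid(pair = seq_len(nrow(ranges)),
                                age_group = ages, year = years)
    frac <- u[pgrid$pair]
    if (config$paf_age_gradient != 0) {
      rel <- (match(pgrid$age_group, ages) - (length(ages) + 1) / 2) /
        (length(ages) - 1)
      frac <- frac * (1 + 2 * config$paf_age_gradient * rel)
    }
    if (config$paf_drift != 0) {
      frac <- frac * (1 + config$paf_drift)^(pgrid$year - years[1])
    }
    paf_parts[[i]] <- tibble::tibble(
      country = cc,
      age_group = pgrid$age_group,
      condition = ranges$condition[pgrid$pair],
      risk_factor = ranges$risk_factor[pgrid$pair],
      year = pgrid$year,
      fraction = pmin(1, pmax(0, frac))
    )

    set.seed(stream_seed(config$seed, "daly", cc))
    size <- config$daly_scale * (group_scale[grp] / group_scale[2]) *
      exp(stats::rnorm(1, 0, 0.3))
    noise <- exp(stats::rnorm(length(ages) * length(conditions()), 0, 0.2))
    dgrid <- tidyr::expand_grid(age_group = ages, condition = conditions(),
                                year = years)
    key <- interaction(dgrid$age_group, dgrid$condition, drop = FALSE)
    dgrid$dalys <- size * cond_w[dgrid$condition] *
      age_w[match(dgrid$age_group, ages)] * noise[as.integer(key)] *
      1.01^(dgrid$year - years[1])
    dgrid$country <- cc
    daly_parts[[i]] <- dgrid[c("country", "age_group", "condition", "year",
                               "dalys")]
  }

  list(
    che = che_series(dplyr::bind_rows(che_parts)),
    paf = paf_series(dplyr::bind_rows(paf_parts)),
    daly = daly_series(dplyr::bind_rows(daly_parts)),
    countries = countries
  )
}

#' Write a generated input set to a directory
#'
#' Emits `che.csv`, `paf.csv`, `daly.csv`, `countries.csv` and a
#' `manifest.json` echoing the seed and configuration. Byte-identical for a
#' fixed seed.
#'
#' @param inputs The list returned by [generate_inputs()].
#' @param dir Output directory (created if needed).
#' @param config The [generator_config()] used, echoed into the manifest.
#' @return `dir`, invisibly.
#' @export
write_inputs <- function(inputs, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_che(inputs$che, file.path(dir, "che.csv"))
  write_paf(inputs$paf, file.path(dir, "paf.csv"))
  write_daly(inputs$daly, file.path(dir, "daly.csv"))
  write_countries(inputs$countries, file.path(dir, "countries.csv"))
  manifest <- list(
    seed = if (!is.null(config)) config$seed else NA,
    config = if (!is.null(config)) {
      cfg <- unclass(config)
      cfg$paf_ranges <- as.data.frame(cfg$paf_ranges)
      cfg
    } else NULL,
    files = c("che.csv", "paf.csv", "daly.csv", "countries.csv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Calibrate synthetic inputs to target cumulative savings
#'
#' Rescales each risk factor's expenditure contribution by a single
#' multiplicative factor so that the model's cumulative discounted savings
#' per risk factor (summed over all countries) match the supplied targets.
#' Because the model is linear in expenditure, scaling a factor's
#' single-factor impact by c is exactly equivalent to running that factor's
#' scenario on expenditure scaled by c; the joint calibrated total is then
#' the sum of the targets, mirroring the additive combined column of the
#' published savings table.
#'
#' @param inputs Input list as returned by [generate_inputs()].
#' @param scenario The [cra_scenario()] the targets refer to (e.g. a 10%
#'   reduction in each factor).
#' @param targets Named numeric vector: risk factor -> target cumulative
#'   discounted savings (million 2018 US$) over all countries.
#' @param conditions_tbl Condition share table.
#' @return A `cra_calibration` list with elements `scale_factors` (named
#'   numeric), `impact` (the calibrated `impact_table`), `totals` (achieved
#'   per-factor totals) and `baseline_totals`.
#' @export
calibrate_to_totals <- function(inputs, scenario, targets,
                                conditions_tbl = default_condition_table()) {
  if (is.null(names(targets)) ||
        !all(names(targets) %in% risk_factors())) {
    stop("`targets` must be named by risk factor", call. = FALSE)
  }
  if (any(targets < 0)) {
    stop("targets must be nonnegative (a nonnegative scaling cannot reach ",
         "a negative total)", call. = FALSE)
  }
  impact <- run_scenario(inputs$che, conditions_tbl, inputs$paf, scenario)
  base_totals <- impact |>
    dplyr::group_by(.data$risk_factor) |>
    dplyr::summarise(total = sum(.data$discounted), .groups = "drop")
  base <- stats::setNames(base_totals$total, base_totals$risk_factor)
  factors <- stats::setNames(rep(1, length(targets)), names(targets))
  for (rf in names(targets)) {
    b <- base[[rf]]
    if (b <= 0) {
      if (targets[[rf]] == 0) {
        factors[rf] <- 0
      } else {
        stop(sprintf(
          "target for %s unreachable: baseline savings are %g", rf, b),
          call. = FALSE)
      }
    } else {
      factors[rf] <- targets[[rf]] / b
    }
  }
  fcol <- factors[impact$risk_factor]
  fcol[is.na(fcol)] <- 1
  calibrated <- impact
  calibrated$undiscounted <- calibrated$undiscounted * fcol
  calibrated$discounted <- calibrated$discounted * fcol
  achieved <- calibrated |>
    dplyr::group_by(.data$risk_factor) |>
    dplyr::summarise(total = sum(.data$discounted), .groups = "drop")
  structure(
    list(scale_factors = factors,
         impact = calibrated,
         totals = stats::setNames(achieved$total, achieved$risk_factor),
         baseline_totals = base),
    class = "cra_calibration"
  )
}
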