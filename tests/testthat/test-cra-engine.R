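test_that("phase-in factor is zero at start, one after the ramp, linear between", {
  expect_equal(ramp_factor(2020, 2020, 10), 0)
  expect_equal(ramp_factor(2030, 2020, 10), 1)
  expect_equal(ramp_factor(2025, 2020, 10), 0.5)
  expect_equal(ramp_factor(2045, 2020, 10), 1)
  expect_equal(ramp_factor(2015, 2020, 10), 0)
  expect_equal(ramp_factor(2020:2030, 2020, 10), seq(0, 1, by = 0.1))
  # a zero-length ramp is a step the year after adoption
  expect_equal(ramp_factor(c(2020, 2021), 2020, 0), c(0, 1))
  expect_error(ramp_factor(2020, 2020, -1), ">= 0")
})

test_that("discount factor follows the closed form (1+r)^-k", {
  expect_equal(discount_factor(2020, 0.03, 2020), 1)
  expect_equal(discount_factor(2045, 0, 2020), 1)
  expect_equal(discount_factor(2022, 0.03, 2020), 1 / 1.0609)
  k <- 0:30
  expect_equal(discount_factor(2020 + k, 0.03, 2020), 1.03^(-k))
  expect_error(discount_factor(2019, 0.03, 2020), "before base_year")
  expect_error(discount_factor(2021, -0.01, 2020), ">= 0")
})

test_that("annual impact is the product of expenditure, share, reduction, PAF and ramp", {
  che <- che_series(data.frame(country = "AA", age_group = 40L,
                               chapter = "IX", year = 2030L, value = 1000))
  paf <- paf_series(data.frame(country = "AA", age_group = 40L,
                               condition = "cvd", risk_factor = "high_sbp",
                               year = 2030L, fraction = 0.5))
  cvd_row <- default_condition_table()[3, ]
  scen <- cra_scenario(c(high_sbp = 0.10))
  imp <- annual_policy_impact(che, cvd_row, paf, scen, 2030)
  cell <- imp$undiscounted[imp$risk_factor == "high_sbp" &
                             imp$condition == "cvd"]
  expect_equal(cell, 1000 * 0.9191 * 0.10 * 0.5) # 45.955, full ramp

  # zero reduction nullifies every cell
  imp0 <- annual_policy_impact(che, cvd_row, paf,
                               cra_scenario(c(high_sbp = 0)), 2030)
  expect_true(all(imp0$undiscounted == 0))

  # degenerate factors: PAF = 1, share = 1, reduction = 0.25 -> 0.25 * CHE
  paf1 <- paf; paf1$fraction <- 1
  full_share <- cvd_row; full_share$share <- 1
  imp25 <- annual_policy_impact(che, full_share, paf1,
                                cra_scenario(c(high_sbp = 0.25)), 2030)
  expect_equal(imp25$undiscounted[imp25$risk_factor == "high_sbp" &
                                    imp25$condition == "cvd"],
               0.25 * 1000)
})

test_that("a condition whose chapter is absent from the expenditure series fails", {
  che <- toy_che(chapters = c("II", "IV", "IX", "X")) # no XIV
  paf <- toy_paf()
  scen <- cra_scenario(c(high_sbp = 0.10))
  err <- expect_error(
    run_scenario(che, default_condition_table(), paf, scen), "absent")
  expect_match(conditionMessage(err), "XIV")
  expect_match(conditionMessage(err), "ckd")
})

test_that("a one-year horizon reduces to a single annual impact call", {
  che <- toy_che(years = 2020:2035)
  paf <- toy_paf(years = 2020:2035)
  scen <- cra_scenario(c(tobacco = 0.10), start_year = 2035,
                       horizon_end = 2035, base_year = 2035)
  full <- run_scenario(che, default_condition_table(), paf, scen)
  annual <- annual_policy_impact(che, default_condition_table(), paf, scen,
                                 2035)
  expect_equal(sorted_impact(full)$undiscounted,
               sorted_impact(annual)$undiscounted)
  expect_equal(full$discounted, full$undiscounted) # base year, factor 1
})

test_that("the joint scenario equals the cellwise sum of single-factor scenarios", {
  inp <- generate_inputs(small_config(seed = 8))
  cond <- default_condition_table()
  joint <- cra_scenario(c(tobacco = 0.10, alcohol = 0.10,
                          high_sbp = 0.10, high_glucose = 0.10))
  combined <- sorted_impact(run_scenario(inp$che, cond, inp$paf, joint))
  acc <- 0
  for (rf in risk_factors()) {
    single <- run_scenario(inp$che, cond, inp$paf,
                           cra_scenario(stats::setNames(0.10, rf)))
    acc <- acc + sorted_impact(single)$undiscounted
  }
  # each single run zeroes the other factors, so the cellwise sum across the
  # four runs must reproduce the joint table (no interaction term)
  expect_equal(acc, combined$undiscounted, tolerance = 1e-12)
})

test_that("impact is linear in the reduction: 25% equals five times 5%", {
  inp <- generate_inputs(small_config(seed = 9))
  cond <- default_condition_table()
  mk <- function(s) cra_scenario(c(tobacco = s, alcohol = s,
                                   high_sbp = s, high_glucose = s))
  i5 <- sorted_impact(run_scenario(inp$che, cond, inp$paf, mk(0.05)))
  i25 <- sorted_impact(run_scenario(inp$che, cond, inp$paf, mk(0.25)))
  expect_gt(sum(i25$undiscounted), 0)
  expect_equal(i25$undiscounted, 5 * i5$undiscounted, tolerance = 1e-12)
  expect_equal(i25$discounted, 5 * i5$discounted, tolerance = 1e-12)
})

test_that("run_scenario matches the independent nested-loop oracle", {
  che <- toy_che(countries = c("AA", "BB"), ages = c(40L, 60L),
                 years = 2020:2022, value = 350)
  # make values heterogeneous so the comparison is not trivial
  set.seed(99)
  che$value <- stats::runif(nrow(che), 50, 500)
  paf <- toy_paf(countries = c("AA", "BB"), ages = c(40L, 60L),
                 years = 2020:2022)
  paf$fraction <- stats::runif(nrow(paf), 0, 0.6)
  scen <- cra_scenario(c(tobacco = 0.10, alcohol = 0.05, high_sbp = 0.25,
                         high_glucose = 0.10),
                       start_year = 2020, horizon_end = 2022)
  got <- sorted_impact(run_scenario(che, default_condition_table(), paf, scen))
  want <- oracle_run_scenario(che, default_condition_table(), paf, scen)
  expect_equal(got$undiscounted, want$undiscounted, tolerance = 1e-12)
  expect_equal(got$discounted, want$discounted, tolerance = 1e-12)
})

test_that("savings are monotone in expenditure, share, reduction and PAF", {
  che <- toy_che(years = 2020:2025)
  paf <- toy_paf(years = 2020:2025, fraction = 0.3)
  cond <- default_condition_table()
  scen <- cra_scenario(c(tobacco = 0.10), horizon_end = 2025)
  base_total <- sum(run_scenario(che, cond, paf, scen)$undiscounted)

  che_up <- che; che_up$value <- che_up$value * 1.5
  expect_gte(sum(run_scenario(che_up, cond, paf, scen)$undiscounted),
             base_total)
  cond_up <- cond; cond_up$share <- pmin(1, cond_up$share * 1.1)
  expect_gte(sum(run_scenario(che, cond_up, paf, scen)$undiscounted),
             base_total)
  expect_gte(sum(run_scenario(che, cond, paf,
                              cra_scenario(c(tobacco = 0.2),
                                           horizon_end = 2025))$undiscounted),
             base_total)
  paf_up <- paf; paf_up$fraction <- pmin(1, paf_up$fraction * 1.2)
  expect_gte(sum(run_scenario(che, cond, paf_up, scen)$undiscounted),
             base_total)
})

test_that("discounting never increases savings and is neutral at rate zero", {
  inp <- generate_inputs(small_config(seed = 10))
  cond <- default_condition_table()
  scen <- cra_scenario(c(high_sbp = 0.10))
  imp <- run_scenario(inp$che, cond, inp$paf, scen)
  pos <- imp$undiscounted > 0
  expect_true(all(imp$discounted[pos] < imp$undiscounted[pos]))
  flat <- run_scenario(inp$che, cond, inp$paf,
                       cra_scenario(c(high_sbp = 0.10), discount_rate = 0))
  expect_identical(flat$discounted, flat$undiscounted)
})

test_that("ramp shortfall on constant inputs matches the discrete closed form", {
  years <- 2020:2050
  che <- toy_che(countries = "AA", ages = 40L, years = years, value = 1000)
  paf <- toy_paf(countries = "AA", ages = 40L, years = years, fraction = 0.4)
  cond <- default_condition_table()
  scen <- cra_scenario(c(tobacco = 0.10), discount_rate = 0)
  total <- sum(run_scenario(che, cond, paf, scen)$undiscounted)
  annual_full <- sum(annual_policy_impact(che, cond, paf, scen, 2050)$undiscounted)
  n_years <- length(years)
  # brute-force year loop oracle
  brute <- sum(vapply(years, function(t) {
    annual_full * min(1, (t - 2020) / 10)
  }, numeric(1)))
  expect_equal(total, brute, tolerance = 1e-12)
  # discrete closed form: full-effect total minus (ramp_years + 1)/2 annual
  # amounts (the continuous-time shortfall would be ramp_years / 2)
  expect_equal(total, annual_full * n_years - annual_full * (10 + 1) / 2,
               tolerance = 1e-12)
})

test_that("percent of cumulative expenditure is invariant to currency rescaling", {
  inp <- generate_inputs(small_config(seed = 12))
  scen <- cra_scenario(c(tobacco = 0.10, high_glucose = 0.10))
  cond <- default_condition_table()
  imp <- run_scenario(inp$che, cond, inp$paf, scen)
  sv <- cumulative_savings(imp, inp$che, scen)
  che2 <- inp$che; che2$value <- che2$value * 7.3
  imp2 <- run_scenario(che2, cond, inp$paf, scen)
  sv2 <- cumulative_savings(imp2, che2, scen)
  expect_equal(sv2$percent, sv$percent, tolerance = 1e-12)
  expect_equal(sv2$savings, 7.3 * sv$savings, tolerance = 1e-12)
})

test_that("cumulative savings sums the horizon and fails on an empty one", {
  che <- toy_che(countries = "AA", ages = 40L, chapters = "IX",
                 years = 2020:2022, value = 50)
  imp <- tibble::tibble(country = "AA", risk_factor = "high_sbp",
                        condition = "cvd", year = 2020:2022,
                        undiscounted = 10, discounted = 10)
  scen <- cra_scenario(c(high_sbp = 0.1), discount_rate = 0,
                       horizon_end = 2022)
  sv <- cumulative_savings(imp, che, scen)
  expect_equal(sv$savings, 30)
  expect_equal(sv$percent, 100 * 30 / sum(che$value))
  zero <- imp; zero$discounted <- 0
  sv0 <- cumulative_savings(zero, che, scen)
  expect_equal(sv0$savings, 0)
  expect_equal(sv0$percent, 0)
  expect_error(cumulative_savings(imp[0, ], che, scen), "empty")
})

test_that("negative reductions produce added expenditure (negative savings)", {
  che <- toy_che(years = 2020:2025)
  paf <- toy_paf(years = 2020:2025, fraction = 0.3)
  scen <- cra_scenario(c(tobacco = -0.10), horizon_end = 2025)
  imp <- run_scenario(che, default_condition_table(), paf, scen)
  expect_lt(sum(imp$undiscounted), 0)
})

test_that("percent DALY reduction is the exact product under uniform fractions", {
  countries <- c("AA", "BB", "CC")
  paf <- toy_paf(countries, years = 2030L,
                 set = list(high_glucose = c(diabetes_t2 = 1.0),
                            tobacco = c(copd = 0.458),
                            high_sbp = c(cvd = 0.5232, ckd = 0.564)))
  daly <- toy_daly(countries, years = 2030L, dalys = 500)
  ds <- daly_reduction(paf, daly, reduction_levels = c(0.10, 0.25))
  cell <- function(k, rf, s) {
    ds$percent[ds$condition == k & ds$risk_factor == rf & ds$level == s]
  }
  expect_equal(round(cell("diabetes_t2", "high_glucose", 0.10), 2), 10.00)
  expect_equal(round(cell("copd", "tobacco", 0.25), 2), 11.45)
  expect_equal(round(cell("cvd", "high_sbp", 0.25), 2), 13.08)
  expect_equal(round(cell("ckd", "high_sbp", 0.25), 2), 14.10)
  # unlinked pairs carry NA; zeroed-out linked pairs are zero
  expect_true(is.na(cell("copd", "alcohol", 0.10)))
  expect_equal(cell("cvd", "alcohol", 0.10), 0)
})

test_that("zero-level DALY reduction is zero and weighting modes differ as expected", {
  inp <- generate_inputs(small_config(seed = 13))
  ds0 <- daly_reduction(inp$paf, inp$daly, reduction_levels = 0)
  expect_true(all(ds0$percent[!is.na(ds0$percent)] == 0))
  expect_error(daly_reduction(inp$paf, inp$daly, reduction_levels = -0.1),
               ">= 0")
  uw <- daly_reduction(inp$paf, inp$daly, reduction_levels = 0.1)
  dw <- daly_reduction(inp$paf, inp$daly, reduction_levels = 0.1,
                       country_weighting = "daly_weighted")
  expect_equal(dim(uw), dim(dw))
})

test_that("countries with zero DALYs are excluded from the average with a warning", {
  countries <- c("AA", "BB")
  paf <- toy_paf(countries, years = 2030L,
                 set = list(tobacco = c(copd = 0.5)))
  # second country contributes PAF 0.9 but has zero COPD DALYs everywhere
  paf$fraction[paf$country == "BB" & paf$condition == "copd" &
                 paf$risk_factor == "tobacco"] <- 0.9
  daly <- toy_daly(countries, years = 2030L, dalys = 100)
  daly$dalys[daly$country == "BB" & daly$condition == "copd"] <- 0
  expect_warning(
    ds <- daly_reduction(paf, daly, reduction_levels = 0.10),
    "zero total DALYs")
  got <- ds$percent[ds$condition == "copd" & ds$risk_factor == "tobacco"]
  expect_equal(got, 0.10 * 0.5 * 100) # only country AA averaged
})
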