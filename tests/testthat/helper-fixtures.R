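# Small in-code fixtures and independent oracles used across the suite.

toy_che <- function(countries = c("AA", "BB"), ages = c(40L, 60L),
                    chapters = c("II", "IV", "IX", "X", "XIV"),
                    years = 2020:2022, value = 100) {
  g <- tidyr::expand_grid(country = countries, age_group = ages,
                          chapter = chapters, year = years)
  g$value <- value
  che_series(g)
}

# constant fraction on every linked pair (or on the pairs given in `set`,
# a named list like list(high_sbp = c(cvd = 0.5)))
toy_paf <- function(countries = c("AA", "BB"), ages = c(40L, 60L),
                    years = 2020:2022, fraction = 0.2, set = NULL) {
  pairs <- link_pairs()
  pairs <- pairs[pairs$linked, ]
  pairs$fraction <- fraction
  if (!is.null(set)) {
    pairs$fraction <- 0
    for (rf in names(set)) {
      for (k in names(set[[rf]])) {
        pairs$fraction[pairs$risk_factor == rf & pairs$condition == k] <-
          set[[rf]][[k]]
      }
    }
  }
  g <- tidyr::expand_grid(country = countries, age_group = ages,
                          year = years,
                          pairs[c("risk_factor", "condition", "fraction")])
  paf_series(g[c("country", "age_group", "condition", "risk_factor",
                 "year", "fraction")])
}

toy_daly <- function(countries = c("AA", "BB"), ages = c(40L, 60L),
                     years = 2020:2022, dalys = 1000) {
  g <- tidyr::expand_grid(country = countries, age_group = ages,
                          condition = conditions(), year = years)
  g$dalys <- dalys
  daly_series(g)
}

# Independent nested-loop implementation of the annual policy-impact
# product, deliberately scalar and join-free. Returns the same keying as
# run_scenario (undiscounted and discounted).
oracle_run_scenario <- function(che, cond_tbl, paf, scen) {
  years <- seq.int(scen$start_year, scen$horizon_end)
  rows <- list()
  for (cc in unique(che$country)) {
    for (p in names(scen$reductions)) {
      for (ki in seq_len(nrow(cond_tbl))) {
        k <- cond_tbl$condition[ki]
        ch <- cond_tbl$chapter[ki]
        sh <- cond_tbl$share[ki]
        for (t in years) {
          tot <- 0
          for (a in unique(che$age_group)) {
            v <- che$value[che$country == cc & che$age_group == a &
                             che$chapter == ch & che$year == t]
            f <- paf$fraction[paf$country == cc & paf$age_group == a &
                                paf$condition == k & paf$risk_factor == p &
                                paf$year == t]
            if (length(v) == 1 && length(f) == 1) {
              r <- if (scen$ramp_years == 0) {
                as.numeric(t > scen$start_year)
              } else {
                min(1, max(0, (t - scen$start_year) / scen$ramp_years))
              }
              tot <- tot + v * sh * scen$reductions[[p]] * f * r
            }
          }
          rows[[length(rows) + 1]] <- data.frame(
            country = cc, risk_factor = p, condition = k, year = t,
            undiscounted = tot,
            discounted = tot * (1 + scen$discount_rate)^
              (-(t - scen$base_year)))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$country, out$risk_factor, out$condition, out$year), ]
}

sorted_impact <- function(x) {
  x <- tibble::as_tibble(x)
  x[order(x$country, x$risk_factor, x$condition, x$year), ]
}

small_config <- function(seed = 1, ...) {
  generator_config(seed = seed, n_latin = 2, n_carib = 1, ...)
}
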