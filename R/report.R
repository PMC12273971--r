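# Report rendering: the two headline table shapes — cumulative discounted
# savings by country and risk factor, and average percent DALY reduction by
# condition, risk factor and reduction level. Rendering is a pure function
# of the summary objects; all aggregation happens before any rounding, so a
# displayed subtotal can differ from the sum of displayed member rows by at
# most one unit in the last place per member.

condition_labels <- function() {
  c(cancer = "Cancer (neoplasms)",
    diabetes_t2 = "Diabetes mellitus type 2",
    cvd = "Cardiovascular diseases",
    copd = "Chronic obstructive pulmonary disease",
    ckd = "Chronic kidney disease")
}

risk_factor_labels <- function() {
  c(tobacco = "Tobacco",
    alcohol = "Alcohol",
    high_sbp = "Hypertension",
    high_glucose = "High blood glucose")
}

#' Savings report table
#'
#' Reshapes a [cumulative_savings()] summary into the published layout: one
#' row per country (alphabetical within region), followed by the two region
#' subtotals and the all-country total; per-risk-factor savings and percent
#' columns, then the combined (all four factors) pair. Subtotals are summed
#' from unrounded member cells.
#'
#' @param savings Per-country summary from [cumulative_savings()] (columns
#'   `country`, `risk_factor`, `savings`, `base_che`, `percent`); any total
#'   rows already present are ignored and recomputed.
#' @param countries A [cra_countries()] register covering the summary.
#' @param include Optional character vector of country codes to restrict the
#'   table to; an unknown code is an error.
#' @return A tibble with a `country` display column and, for each risk
#'   factor plus `combined`, `savings_*` and `percent_*` columns (unrounded).
#' @export
savings_table <- function(savings, countries, include = NULL) {
  countries <- cra_countries(countries)
  savings <- dplyr::filter(savings, .data$country %in% countries$code)
  if (!is.null(include)) {
    unknown <- setdiff(include, countries$code)
    if (length(unknown) > 0) {
      stop("unknown country code(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    countries <- dplyr::filter(countries, .data$code %in% include)
    savings <- dplyr::filter(savings, .data$country %in% include)
  }
  missing <- setdiff(countries$code, unique(savings$country))
  if (length(missing) > 0) {
    stop("summary does not cover country code(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  wide_one <- function(sv, label) {
    denom <- sum(dplyr::distinct(sv, .data$country, .data$base_che)$base_che)
    per_rf <- sv |>
      dplyr::group_by(.data$risk_factor) |>
      dplyr::summarise(savings = sum(.data$savings), .groups = "drop")
    row <- tibble::tibble(country = label)
    for (rf in risk_factors()) {
      s <- per_rf$savings[per_rf$risk_factor == rf]
      s <- if (length(s) == 0) 0 else s
      row[[paste0("savings_", rf)]] <- s
      row[[paste0("percent_", rf)]] <- 100 * s / denom
    }
    row$savings_combined <- sum(per_rf$savings)
    row$percent_combined <- 100 * row$savings_combined / denom
    row
  }

  rows <- list()
  for (reg in c("latin_america", "caribbean")) {
    cc <- dplyr::filter(countries, .data$region == reg)
    cc <- cc[order(cc$name), ]
    for (j in seq_len(nrow(cc))) {
      sv <- dplyr::filter(savings, .data$country == cc$code[j])
      rows[[length(rows) + 1]] <- wide_one(sv, cc$name[j])
    }
    if (nrow(cc) > 0) {
      sv <- dplyr::filter(savings, .data$country %in% cc$code)
      label <- if (reg == "latin_america") "All Latin American countries"
               else "All Caribbean countries"
      rows[[length(rows) + 1]] <- wide_one(sv, label)
    }
  }
  rows[[length(rows) + 1]] <- wide_one(savings, "All countries")
  dplyr::bind_rows(rows)
}

#' DALY reduction report table
#'
#' Reshapes a [daly_reduction()] summary into the published layout: one row
#' per condition, one column block per risk factor with one column per
#' reduction level. Cells where the risk factor is not linked to the
#' condition are `NA` (rendered blank).
#'
#' @param summary A `daly_summary` from [daly_reduction()].
#' @return A tibble with a `condition` display column and one numeric column
#'   per (risk factor, level), named like `tobacco_10` (percent, unrounded).
#' @export
daly_table <- function(summary) {
  levels <- sort(unique(summary$level))
  out <- summary |>
    dplyr::mutate(col = paste0(.data$risk_factor, "_",
                               format(100 * .data$level, trim = TRUE))) |>
    dplyr::select("condition", "col", "percent") |>
    tidyr::pivot_wider(names_from = "col", values_from = "percent")
  # order: published condition order; column blocks in risk-factor order
  out <- out[match(conditions(), out$condition), ]
  ord <- as.vector(t(outer(risk_factors(),
                           format(100 * levels, trim = TRUE),
                           paste, sep = "_")))
  out <- out[c("condition", intersect(ord, names(out)))]
  out$condition <- unname(condition_labels()[out$condition])
  out
}

fmt_thousands <- function(x, digits = 0) {
  format(round(x, digits), big.mark = ",", scientific = FALSE, trim = TRUE)
}

render_markdown_table <- function(df) {
  cells <- lapply(df, function(col) {
    out <- as.character(col)
    out[is.na(col)] <- ""
    out
  })
  m <- do.call(cbind, cells)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(m, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                         " |"))
  c(header, sep, body)
}

#' Render report tables to text
#'
#' `render_savings_markdown()` renders a [savings_table()] with savings
#' rounded to integer millions (thousands separators) and percents to two
#' decimals; `render_daly_markdown()` renders a [daly_table()] with percents
#' to two decimals and blanks on unlinked cells. CSV output keeps full
#' precision and no separators (machine-facing).
#'
#' @param tbl The table to render.
#' @return Character vector of markdown lines.
#' @export
render_savings_markdown <- function(tbl) {
  disp <- tibble::tibble(Country = tbl$country)
  labels <- c(risk_factor_labels(), combined = "All four risk factors")
  for (rf in c(risk_factors(), "combined")) {
    disp[[labels[[rf]]]] <- fmt_thousands(tbl[[paste0("savings_", rf)]])
    disp[[paste0(labels[[rf]], " (%)")]] <-
      sprintf("%.2f%%", tbl[[paste0("percent_", rf)]])
  }
  render_markdown_table(disp)
}

#' @rdname render_savings_markdown
#' @export
render_daly_markdown <- function(tbl) {
  disp <- tibble::tibble(Condition = tbl$condition)
  labels <- risk_factor_labels()
  for (col in setdiff(names(tbl), "condition")) {
    rf <- sub("_[0-9.]+$", "", col)
    lev <- sub("^.*_", "", col)
    nm <- sprintf("%s %s%%", labels[[rf]], lev)
    disp[[nm]] <- ifelse(is.na(tbl[[col]]), "",
                         sprintf("%.2f", tbl[[col]]))
  }
  render_markdown_table(disp)
}
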