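#' Risk factors in the comparative risk assessment
#'
#' The four modifiable risk factors considered: tobacco use, harmful alcohol
#' use, high systolic blood pressure and high blood glucose. The two metabolic
#' factors stand in for the diet and physical-activity "best buys", whose
#' burden estimates have known cross-country comparability issues.
#'
#' @return Character vector of the four risk factor identifiers.
#' @export
#' @examples
#' risk_factors()
risk_factors <- function() {
  c("tobacco", "alcohol", "high_sbp", "high_glucose")
}

#' Conditions (outcomes) in the comparative risk assessment
#'
#' @return Character vector of the five condition identifiers: cancer
#'   (neoplasms), type 2 diabetes mellitus, cardiovascular disease, chronic
#'   obstructive pulmonary disease and chronic kidney disease.
#' @export
conditions <- function() {
  c("cancer", "diabetes_t2", "cvd", "copd", "ckd")
}

#' Five-year age groups
#'
#' Lower bounds of the 18 five-year age bands, 0-4 through 85+ (the last band
#' is open-ended).
#'
#' @return Integer vector of length 18: 0, 5, ..., 85.
#' @export
age_groups <- function() {
  seq.int(0L, 85L, by = 5L)
}

#' ICD-10 chapters carried by expenditure series
#'
#' Roman-numeral codes for the 21 ICD-10 chapters with usable prevalence
#' data. Only the five chapters mapped to conditions (II, IV, IX, X, XIV)
#' enter the policy-impact computation; the rest are carried so that
#' percent-of-total-expenditure denominators can be computed.
#'
#' @return Character vector of Roman-numeral chapter codes "I".."XXI".
#' @export
icd_chapters <- function() {
  as.character(utils::as.roman(1:21))
}

#' Condition-to-chapter cost share table
#'
#' Each condition is located within one ICD-10 chapter and represents a fixed
#' share of that chapter's expenditure. The default shares are the 2015-2019
#' national averages estimated from Colombia's RIPS administrative records and
#' applied to all countries: cancer spans its entire chapter (share 1), the
#' other conditions a fraction of theirs. Shares are stored as fractions, not
#' percentages; percentage formatting happens only in reporting.
#'
#' @param shares Optional named numeric vector overriding the default shares
#'   (names must be the five condition identifiers, values in (0, 1]).
#' @return A tibble with columns `condition`, `chapter`, `share`.
#' @export
#' @examples
#' default_condition_table()
default_condition_table <- function(shares = NULL) {
  tbl <- tibble::tibble(
    condition = conditions(),
    chapter   = c("II", "IV", "IX", "X", "XIV"),
    share     = c(1.0000, 0.2485, 0.9191, 0.3689, 0.372)
  )
  if (!is.null(shares)) {
    if (is.null(names(shares)) || !all(names(shares) %in% tbl$condition)) {
      stop("`shares` must be named by condition: ",
           paste(tbl$condition, collapse = ", "), call. = FALSE)
    }
    if (any(shares <= 0 | shares > 1)) {
      stop("condition shares must lie in (0, 1]", call. = FALSE)
    }
    tbl$share[match(names(shares), tbl$condition)] <- unname(shares)
  }
  tbl
}

#' Risk factor to condition link matrix
#'
#' Which risk factors act on which conditions. A policy impact and an
#' attributable-DALY fraction exist only where the link is `TRUE`; PAF series
#' must be exactly zero elsewhere. There are 12 linked pairs: tobacco acts on
#' CVD, cancer, COPD and diabetes; high systolic blood pressure on CVD and
#' CKD; high blood glucose on CVD, cancer, diabetes and CKD; alcohol on CVD
#' and cancer.
#'
#' @return A logical matrix with risk factors as rows and conditions as
#'   columns.
#' @export
#' @examples
#' link_matrix()
link_matrix <- function() {
  m <- matrix(FALSE, nrow = 4L, ncol = 5L,
              dimnames = list(risk_factors(), conditions()))
  m["tobacco",      c("cvd", "cancer", "copd", "diabetes_t2")] <- TRUE
  m["high_sbp",     c("cvd", "ckd")] <- TRUE
  m["high_glucose", c("cvd", "cancer", "diabetes_t2", "ckd")] <- TRUE
  m["alcohol",      c("cvd", "cancer")] <- TRUE
  m
}

#' Linked (risk factor, condition) pairs as a tibble
#'
#' Long-format view of [link_matrix()], convenient for joins.
#'
#' @param links Logical link matrix; defaults to [link_matrix()].
#' @return A tibble with columns `risk_factor`, `condition`, `linked`.
#' @export
link_pairs <- function(links = link_matrix()) {
  tibble::tibble(
    risk_factor = rep(rownames(links), times = ncol(links)),
    condition   = rep(colnames(links), each = nrow(links)),
    linked      = as.vector(links)
  )
}
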