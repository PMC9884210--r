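#' Define a categorical study variable
#'
#' A variable specification carries the ordered category labels used
#' throughout the pipeline and, for variables measured on a numeric scale,
#' the coding rule that maps raw measurements onto those categories.
#'
#' @param name Variable name (single string).
#' @param states Ordered character vector of category labels (at least two,
#'   all distinct).
#' @param role One of `"exposure"`, `"outcome"`, `"demographic"`.
#' @param coding Optional [coding_rule()] whose labels are exactly `states`
#'   in interval order.
#' @return An object of class `variable_spec`.
#' @seealso [hhcy_schema()] for the full clinical variable set.
#' @export
variable_spec <- function(name, states,
                          role = c("exposure", "outcome", "demographic"),
                          coding = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  states <- as.character(states)
  if (length(states) < 2L) {
    abort(sprintf("variable '%s' needs at least 2 states", name))
  }
  if (anyDuplicated(states)) {
    abort(sprintf("variable '%s' has duplicate state labels", name))
  }
  if (!is.null(coding)) {
    stopifnot(inherits(coding, "coding_rule"))
    if (!identical(coding$labels, states)) {
      abort(sprintf("coding rule labels for '%s' must equal its states", name))
    }
  }
  structure(list(name = name, states = states, role = role, coding = coding),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s (%s): %s\n",
              x$name, x$role, paste(x$states, collapse = " | ")))
  invisible(x)
}

#' Numeric-to-category coding rule
#'
#' Cut-offs partition the real line into `length(cuts) + 1` intervals, one
#' per label. By default every cut-off belongs to the interval above it
#' (lower-closed, `[a, b)`); setting `lower_closed[i] = FALSE` attaches the
#' i-th cut-off to the interval below (so "greater than" definitions such as
#' homocysteine > 15 umol/L place 15 itself in the normal band).
#'
#' @param cuts Strictly increasing numeric cut-offs.
#' @param labels One label per interval, `length(cuts) + 1` of them.
#' @param lower_closed Logical vector, one flag per cut-off (recycled from a
#'   single value). `TRUE` means the cut belongs to the upper interval.
#' @param units Optional measurement units (string, documentation only).
#' @return An object of class `coding_rule`.
#' @examples
#' bmi <- coding_rule(c(18.5, 24, 28),
#'                    c("Underweight", "Normal", "Overweight", "Obesity"),
#'                    units = "kg/m2")
#' code_value(25, bmi)
#' @export
coding_rule <- function(cuts, labels, lower_closed = TRUE, units = NULL) {
  cuts <- as.numeric(cuts)
  if (length(cuts) < 1L || is.unsorted(cuts, strictly = TRUE)) {
    abort("cut-offs must be strictly increasing")
  }
  labels <- as.character(labels)
  if (length(labels) != length(cuts) + 1L) {
    abort("need exactly one label per interval (length(cuts) + 1)")
  }
  lower_closed <- rep_len(as.logical(lower_closed), length(cuts))
  structure(list(cuts = cuts, labels = labels,
                 lower_closed = lower_closed, units = units),
            class = "coding_rule")
}

#' @export
print.coding_rule <- function(x, ...) {
  k <- length(x$cuts)
  lo <- c("(-Inf", sprintf(ifelse(x$lower_closed, "[%g", "(%g"), x$cuts))
  hi <- c(sprintf(ifelse(x$lower_closed, "%g)", "%g]"), x$cuts), "Inf)")
  cat(sprintf("<coding_rule>%s\n",
              if (is.null(x$units)) "" else paste0(" [", x$units, "]")))
  cat(sprintf("  %s, %s -> %s\n", lo, hi, x$labels), sep = "")
  invisible(x)
}

#' Code numeric measurements into categories
#'
#' Total on finite reals: every finite `x` falls in exactly one interval of
#' the rule. Non-finite values are an error.
#'
#' @param x Numeric vector of raw measurements.
#' @param rule A [coding_rule()].
#' @return Character vector of category labels, same length as `x`.
#' @export
code_value <- function(x, rule) {
  stopifnot(inherits(rule, "coding_rule"))
  x <- as.numeric(x)
  if (any(!is.finite(x))) {
    abort("measurements must be finite to be coded")
  }
  # interval index: number of cuts at or below x, with the boundary itself
  # counting only when the cut is lower-closed
  idx <- rep_len(1L, length(x))
  for (i in seq_along(rule$cuts)) {
    past <- if (rule$lower_closed[i]) x >= rule$cuts[i] else x > rule$cuts[i]
    idx <- idx + past
  }
  rule$labels[idx]
}

#' Urinary protein-to-creatinine ratios
#'
#' ACR = mAlb / Ucr x 8.84 and MCR = alpha1-MG / Ucr x 8.84, both in mg/g,
#' converting mg/L analyte concentrations against urine creatinine in
#' mmol/L. Downstream coding treats ACR >= 30 mg/g and MCR > 23 mg/g as
#' abnormal.
#'
#' @param mAlb Urine microalbumin, mg/L.
#' @param alpha1MG Urine alpha1-microglobulin, mg/L.
#' @param Ucr Urine creatinine, mmol/L (must be positive).
#' @return A tibble with columns `ACR` and `MCR` (mg/g).
#' @export
derive_ratios <- function(mAlb, alpha1MG, Ucr) {
  if (any(!is.finite(Ucr)) || any(Ucr <= 0)) {
    abort("urine creatinine must be positive")
  }
  tibble::tibble(ACR = mAlb / Ucr * 8.84, MCR = alpha1MG / Ucr * 8.84)
}

#' Clinical variable schema for the homocysteine study
#'
#' The 20 categorical risk-factor variables plus the homocysteine outcome,
#' with guideline cut-offs where the variable is measured on a numeric
#' scale. Interval closure follows the explicit inequalities of the
#' guideline definitions (e.g. SBP High is >= 140 mmHg so Normal is
#' [120, 140); hyperhomocysteinemia is strictly > 15 umol/L so 15.0 codes
#' Normal); bands written without closure adopt lower-closed/upper-open.
#'
#' @return Named list of [variable_spec()] objects in Table-order.
#' @export
hhcy_schema <- function() {
  specs <- list(
    variable_spec("Sex", c("Male", "Female"), "demographic"),
    variable_spec("Age", c("40-50", "51-60", "61-70", "71-91"), "demographic",
                  coding_rule(c(51, 61, 71),
                              c("40-50", "51-60", "61-70", "71-91"),
                              units = "years")),
    variable_spec("Education", c("Primary", "Middle", "High", "Bachelor"),
                  "demographic"),
    variable_spec("Income", c("<5k", "5k-10k", "10k-20k", ">20k"),
                  "demographic"),
    variable_spec("Exercise", c("No", "Yes")),
    variable_spec("TG", c("No", "Yes"),
                  coding = coding_rule(2.26, c("No", "Yes"),
                                       units = "mmol/L")),
    variable_spec("TC", c("No", "Yes"),
                  coding = coding_rule(6.22, c("No", "Yes"),
                                       units = "mmol/L")),
    variable_spec("LDL", c("No", "Yes"),
                  coding = coding_rule(4.14, c("No", "Yes"),
                                       units = "mmol/L")),
    variable_spec("HDL", c("Yes", "No"),
                  coding = coding_rule(1.04, c("Yes", "No"),
                                       units = "mmol/L")),
    variable_spec("FPG", c("Normal", "Impaired", "High"),
                  coding = coding_rule(c(6.1, 7.0),
                                       c("Normal", "Impaired", "High"),
                                       lower_closed = c(TRUE, FALSE),
                                       units = "mmol/L")),
    variable_spec("GHb", c("No", "Yes"),
                  coding = coding_rule(6.5, c("No", "Yes"), units = "%")),
    variable_spec("SBP", c("Low", "Normal", "High"),
                  coding = coding_rule(c(120, 140),
                                       c("Low", "Normal", "High"),
                                       units = "mmHg")),
    variable_spec("DBP", c("Low", "Normal", "High"),
                  coding = coding_rule(c(80, 90),
                                       c("Low", "Normal", "High"),
                                       units = "mmHg")),
    variable_spec("BMI", c("Underweight", "Normal", "Overweight", "Obesity"),
                  coding = coding_rule(c(18.5, 24, 28),
                                       c("Underweight", "Normal",
                                         "Overweight", "Obesity"),
                                       units = "kg/m2")),
    variable_spec("Smoking", c("No", "Yes")),
    variable_spec("Alcohol", c("Seldom", "Sometimes", "Always")),
    variable_spec("Salt", c("Light", "Balanced", "Salt")),
    variable_spec("Diet", c("Vegetable", "Balanced", "Meat")),
    variable_spec("ACR", c("Normal", "Abnormal"),
                  coding = coding_rule(30, c("Normal", "Abnormal"),
                                       units = "mg/g")),
    variable_spec("MCR", c("Normal", "Abnormal"),
                  coding = coding_rule(23, c("Normal", "Abnormal"),
                                       lower_closed = FALSE,
                                       units = "mg/g")),
    variable_spec("Hcy", c("Normal", "HHcy"), "outcome",
                  coding_rule(15, c("Normal", "HHcy"),
                              lower_closed = FALSE, units = "umol/L"))
  )
  setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Serialize a schema to JSON
#'
#' @param schema Named list of [variable_spec()]s, e.g. [hhcy_schema()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
schema_to_json <- function(schema, path = NULL) {
  enc <- purrr::map(schema, function(v) {
    list(name = v$name, states = v$states, role = v$role,
         coding = if (!is.null(v$coding)) {
           list(cuts = v$coding$cuts, labels = v$coding$labels,
                lower_closed = v$coding$lower_closed,
                units = v$coding$units)
         })
  })
  json <- jsonlite::toJSON(enc, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
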