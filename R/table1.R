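#' Published group-wise counts for the worked examples
#'
#' The baseline-characteristics table of the source study cross-tabulates
#' each of the 20 categorical variables against homocysteine status
#' (Normal, N = 4110; HHcy, N = 8175). These printed counts drive the
#' worked-example tests and the marginal calibration of
#' [make_hhcy_population()].
#'
#' @return A tibble with columns `variable`, `state`, `normal`, `hhcy`.
#' @export
table1_counts <- function() {
  tribble_rows <- list(
    c("Sex", "Male", 1195, 4011),
    c("Sex", "Female", 2915, 4164),
    c("Age", "40-50", 1113, 1585),
    c("Age", "51-60", 1584, 2907),
    c("Age", "61-70", 1075, 2568),
    c("Age", "71-91", 338, 1115),
    c("Education", "Primary", 1199, 2816),
    c("Education", "Middle", 2154, 4101),
    c("Education", "High", 541, 919),
    c("Education", "Bachelor", 216, 339),
    c("Income", "<5k", 1742, 3399),
    c("Income", "5k-10k", 897, 2232),
    c("Income", "10k-20k", 467, 805),
    c("Income", ">20k", 1004, 1739),
    c("Exercise", "No", 2420, 4752),
    c("Exercise", "Yes", 1690, 3423),
    c("TG", "No", 3159, 6437),
    c("TG", "Yes", 951, 1738),
    c("TC", "No", 3918, 7862),
    c("TC", "Yes", 192, 313),
    c("LDL", "No", 3978, 7990),
    c("LDL", "Yes", 132, 185),
    c("HDL", "No", 3464, 6540),
    c("HDL", "Yes", 646, 1635),
    c("FPG", "Normal", 3519, 7382),
    c("FPG", "Impaired", 305, 413),
    c("FPG", "High", 286, 380),
    c("GHb", "No", 3577, 7407),
    c("GHb", "Yes", 533, 768),
    c("SBP", "Low", 701, 1130),
    c("SBP", "Normal", 2016, 3694),
    c("SBP", "High", 1393, 3351),
    c("DBP", "Low", 1514, 2868),
    c("DBP", "Normal", 1670, 3204),
    c("DBP", "High", 926, 2103),
    c("BMI", "Underweight", 73, 129),
    c("BMI", "Normal", 1655, 3203),
    c("BMI", "Overweight", 1772, 3455),
    c("BMI", "Obesity", 610, 1388),
    c("Smoking", "No", 3454, 5905),
    c("Smoking", "Yes", 656, 2270),
    c("Alcohol", "Seldom", 3680, 6729),
    c("Alcohol", "Sometimes", 379, 1237),
    c("Alcohol", "Always", 51, 209),
    c("Salt", "Light", 972, 2263),
    c("Salt", "Balanced", 2686, 4751),
    c("Salt", "Salt", 452, 1161),
    c("Diet", "Vegetable", 1105, 3011),
    c("Diet", "Balanced", 2832, 4770),
    c("Diet", "Meat", 173, 394),
    c("ACR", "Normal", 3600, 7117),
    c("ACR", "Abnormal", 510, 1058),
    c("MCR", "Normal", 3710, 7129),
    c("MCR", "Abnormal", 400, 1046)
  )
  tibble::tibble(
    variable = vapply(tribble_rows, `[[`, "", 1L),
    state = vapply(tribble_rows, `[[`, "", 2L),
    normal = as.numeric(vapply(tribble_rows, `[[`, "", 3L)),
    hhcy = as.numeric(vapply(tribble_rows, `[[`, "", 4L))
  )
}

#' Per-variable published contingency tables
#'
#' @return Named list of [contingency_table()] objects, one per risk-factor
#'   variable, each crossing the variable's states (rows) against
#'   homocysteine status (columns Normal, HHcy).
#' @export
table1_tables <- function() {
  counts <- table1_counts()
  purrr::map(split(counts, factor(counts$variable,
                                  levels = unique(counts$variable))),
             function(d) {
               m <- cbind(Normal = d$normal, HHcy = d$hhcy)
               rownames(m) <- d$state
               contingency_table(m)
             })
}
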