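test_that("guideline cut-offs code boundary measurements correctly", {
  sch <- hhcy_schema()
  # explicit inequalities from the clinical definitions
  expect_equal(code_value(25.0, sch$BMI$coding), "Overweight")
  expect_equal(code_value(140, sch$SBP$coding), "High")
  expect_equal(code_value(6.0, sch$FPG$coding), "Normal")
  expect_equal(code_value(7.0, sch$FPG$coding), "Impaired")  # High is > 7.0
  expect_equal(code_value(15.0, sch$Hcy$coding), "Normal")   # HHcy is > 15
  expect_equal(code_value(15.000001, sch$Hcy$coding), "HHcy")
  expect_equal(code_value(23, sch$MCR$coding), "Normal")     # abnormal > 23
  expect_equal(code_value(30, sch$ACR$coding), "Abnormal")   # abnormal >= 30
  expect_error(code_value(NaN, sch$BMI$coding), "finite")
  expect_error(code_value(Inf, sch$BMI$coding), "finite")
})

test_that("coding is total and agrees with interval membership everywhere", {
  sch <- hhcy_schema()
  rules <- purrr::compact(purrr::map(sch, "coding"))
  set.seed(31)
  for (rule in rules) {
    lo <- min(rule$cuts) - 10
    hi <- max(rule$cuts) + 10
    x <- runif(10000, lo, hi)
    got <- code_value(x, rule)
    # oracle: explicit interval membership per point
    bounds <- c(-Inf, rule$cuts, Inf)
    want <- vapply(x, function(xi) {
      for (k in seq_along(rule$labels)) {
        lo_ok <- if (k == 1L) TRUE else {
          if (rule$lower_closed[k - 1L]) xi >= bounds[k] else xi > bounds[k]
        }
        hi_ok <- if (k == length(rule$labels)) TRUE else {
          if (rule$lower_closed[k]) xi < bounds[k + 1L] else xi <= bounds[k + 1L]
        }
        if (lo_ok && hi_ok) return(rule$labels[k])
      }
      NA_character_
    }, character(1))
    expect_identical(got, want)
    # boundary neighbours fall in adjacent categories
    eps <- 1e-9
    for (i in seq_along(rule$cuts)) {
      below <- code_value(rule$cuts[i] - eps, rule)
      above <- code_value(rule$cuts[i] + eps, rule)
      expect_equal(match(above, rule$labels) - match(below, rule$labels), 1L)
    }
  }
})

test_that("variable_spec and coding_rule reject malformed definitions", {
  expect_error(variable_spec("X", "only-one"), "at least 2")
  expect_error(variable_spec("X", c("a", "a")), "duplicate")
  expect_error(coding_rule(c(2, 1), c("a", "b", "c")), "increasing")
  expect_error(coding_rule(1, c("a", "b", "c")), "one label per interval")
  expect_error(
    variable_spec("X", c("a", "b"), coding = coding_rule(1, c("b", "a"))),
    "must equal its states")
})

test_that("urinary ratios follow the published formula and cut-offs", {
  sch <- hhcy_schema()
  r <- derive_ratios(mAlb = 34, alpha1MG = 0, Ucr = 10)
  expect_equal(r$ACR, 34 / 10 * 8.84)          # 30.056
  expect_equal(r$MCR, 0)
  expect_equal(code_value(r$ACR, sch$ACR$coding), "Abnormal")
  expect_equal(code_value(r$MCR, sch$MCR$coding), "Normal")
  # boundary arithmetic: 33.9/10*8.84 = 29.9676 < 30
  r2 <- derive_ratios(33.9, 50, 10)
  expect_lt(r2$ACR, 30)
  expect_equal(code_value(r2$ACR, sch$ACR$coding), "Normal")
  expect_error(derive_ratios(10, 10, 0), "positive")
  expect_error(derive_ratios(10, 10, -1), "positive")
})

test_that("schema covers the full variable set and serialises to JSON", {
  sch <- hhcy_schema()
  expect_length(sch, 21L)
  expect_equal(sch$Hcy$role, "outcome")
  expect_true(all(vapply(sch, function(v) length(v$states) >= 2L, TRUE)))
  js <- jsonlite::fromJSON(schema_to_json(sch), simplifyVector = FALSE)
  expect_length(js, 21L)
  expect_equal(js$SBP$coding$cuts, list(120, 140))
})
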