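test_that("a single binary predictor recovers the closed-form log odds ratio", {
  # 2x2 counts (a, b; c, d): the logistic slope is ln(ad/bc)
  counts <- list(c(40, 25, 31, 52), c(100, 40, 60, 90), c(7, 13, 21, 9))
  for (ct in counts) {
    a <- ct[1]; b <- ct[2]; c_ <- ct[3]; d <- ct[4]
    dat <- tibble::tibble(
      X = factor(rep(c("x0", "x0", "x1", "x1"), times = ct)),
      Y = factor(rep(c("y0", "y1", "y0", "y1"), times = ct)))
    fit <- fit_logistic(dat, "Y", "X")
    slope <- fit$table$B[fit$table$term == "X"]
    expect_equal(slope, log(a * d / (b * c_)), tolerance = 1e-8)
    expect_true(fit$converged)
    expect_lte(fit$loglik, 0)
  }
})

test_that("degenerate designs are rejected", {
  dat <- tibble::tibble(X = factor(c("a", "b", "a", "b")),
                        Y = factor(rep("y1", 4), c("y0", "y1")))
  expect_error(fit_logistic(dat, "Y", "X"), "constant")
  dat2 <- tibble::tibble(
    X = factor(c("a", "b", "a", "b", "a", "b")),
    X2 = factor(c("a", "b", "a", "b", "a", "b")),   # duplicate of X
    Y = factor(c("y0", "y1", "y1", "y0", "y0", "y1")))
  expect_error(fit_logistic(dat2, "Y", c("X", "X2")), "collinear")
})

test_that("coefficients recover generating values within 3 SE", {
  set.seed(23)
  n <- 20000
  x1 <- sample(0:3, n, replace = TRUE)
  x2 <- rbinom(n, 1, 0.4)
  x3 <- sample(0:2, n, replace = TRUE)
  truth <- c(0.3, -0.8, 0.5)
  eta <- -0.4 + truth[1] * x1 + truth[2] * x2 + truth[3] * x3
  y <- rbinom(n, 1, plogis(eta))
  dat <- tibble::tibble(
    A = factor(x1, 0:3), B = factor(x2, 0:1), C = factor(x3, 0:2),
    Y = factor(y, 0:1))
  fit <- tidy(fit_logistic(dat, "Y", c("A", "B", "C")))
  for (i in seq_along(truth)) {
    row <- fit[fit$term == c("A", "B", "C")[i], ]
    expect_lt(abs(row$B - truth[i]), 3 * row$SE)
  }
})

test_that("odds-ratio arithmetic matches the published table rows", {
  sex <- odds_ratio(-0.777, 0.053)
  expect_equal(round(sex$OR, 3), 0.460)
  expect_equal(round(sex$CI_low, 3), 0.414)
  expect_equal(round(sex$CI_high, 3), 0.510)
  age <- odds_ratio(0.237, 0.022)
  expect_equal(round(age$OR, 3), 1.267)
  null <- odds_ratio(0, 0.1)
  expect_equal(null$OR, 1)
  expect_equal(null$CI_low * null$CI_high, 1, tolerance = 1e-12)
  # log(OR) inverts exp(B)
  expect_equal(log(odds_ratio(1.234, 1)$OR), 1.234)
  expect_error(odds_ratio(1, 0), "positive")
})

test_that("maximised log-likelihood never decreases when a term is added", {
  set.seed(41)
  d <- independent_dataset(500, k_vars = 4, n_states = 3, seed = 41)
  d$Y <- factor(rbinom(500, 1, 0.4), 0:1)
  vars <- paste0("X", 1:4)
  for (k in 1:3) {
    sub <- sample(vars, k)
    extra <- sample(setdiff(vars, sub), 1)
    ll_small <- fit_logistic(d, "Y", sub)$loglik
    ll_big <- fit_logistic(d, "Y", c(sub, extra))$loglik
    expect_gte(ll_big, ll_small - 1e-8)
  }
})

test_that("stepwise selects the true support, matching best-subset BIC", {
  set.seed(57)
  n <- 4000
  k <- 8
  x <- matrix(sample(0:1, n * k, replace = TRUE), n, k)
  eta <- -0.3 + 0.7 * x[, 2] - 0.9 * x[, 5] + 0.6 * x[, 7]
  y <- rbinom(n, 1, plogis(eta))
  d <- tibble::as_tibble(as.data.frame(lapply(
    seq_len(k), function(j) factor(x[, j], 0:1))))
  names(d) <- paste0("X", seq_len(k))
  d$Y <- factor(y, 0:1)
  sel <- stepwise_select(d, "Y", paste0("X", seq_len(k)))
  expect_setequal(sel$selected, c("X2", "X5", "X7"))
  expect_true(all(c("add") %in% sel$trace$action))
  # oracle: exhaustive best-subset under BIC agrees on the support
  best <- NULL; best_bic <- Inf
  for (mask in 0:(2^k - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(k - 1))) > 0)
    sub <- if (length(idx)) paste0("X", idx) else character(0)
    f <- fit_logistic(d, "Y", sub)
    bic <- -2 * f$loglik + log(n) * f$df
    if (bic < best_bic) { best_bic <- bic; best <- sub }
  }
  expect_setequal(best, sel$selected)
  # determinism: identical rerun gives an identical trace
  sel2 <- stepwise_select(d, "Y", paste0("X", seq_len(k)))
  expect_identical(sel$trace, sel2$trace)
})

test_that("stepwise returns nothing when no candidate clears entry", {
  d <- independent_dataset(800, k_vars = 5, seed = 3)
  set.seed(3)
  d$Y <- factor(rbinom(800, 1, 0.5), 0:1)
  sel <- stepwise_select(d, "Y", paste0("X", 1:5), alpha_in = 1e-6)
  expect_length(sel$selected, 0L)
  # a single strongly associated candidate enters in one step
  d2 <- d
  d2$X1 <- factor(ifelse(runif(800) < 0.8, as.integer(d2$Y) - 1L,
                         rbinom(800, 1, 0.5)), 0:1)
  sel2 <- stepwise_select(d2, "Y", paste0("X", 1:5))
  expect_true("X1" %in% sel2$selected)
  expect_equal(sel2$trace$variable[1], "X1")
})
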