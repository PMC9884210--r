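test_that("sampling is reproducible and seeds matter", {
  bn <- random_bn(4, seed = 14)
  a <- sample_bn(bn, 500, seed = 7)
  b <- sample_bn(bn, 500, seed = 7)
  expect_identical(a, b)
  c_ <- sample_bn(bn, 500, seed = 8)
  expect_false(identical(a, c_))
})

test_that("deterministic CPTs force every row to the same configuration", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  st <- list(A = c("x", "y"), B = c("u", "v"))
  bn <- bayesian_network(g, st, list(A = c(0, 1),
                                     B = rbind(c(1, 0), c(0, 1))))
  d <- sample_bn(bn, 50, seed = 1)
  expect_true(all(d$A == "y"))
  expect_true(all(d$B == "v"))           # B copies A's index
})

test_that("empirical conditionals converge to the generating CPT", {
  g <- dag(c("X", "Y"), rbind(c("X", "Y")))
  st <- list(X = c("0", "1"), Y = c("0", "1"))
  bn <- bayesian_network(g, st, list(X = c(0.5, 0.5),
                                     Y = rbind(c(0.7, 0.2), c(0.3, 0.8))))
  d <- sample_bn(bn, 200000, seed = 3)
  emp <- mean(d$Y[d$X == "1"] == "1")
  expect_lt(abs(emp - 0.8), 0.005)       # ~4 binomial SEs at this n
  # wider check across a multi-parent family of the study generator
  truth <- hhcy_truth_network()$network
  big <- sample_bn(truth, 200000, seed = 4)
  for (v in c("SBP", "FPG", "Smoking")) {
    refit <- fit_mle(big, truth$dag)
    est <- matrix(refit$cpts[[v]], nrow = length(truth$states[[v]]))
    tr <- matrix(truth$cpts[[v]], nrow = length(truth$states[[v]]))
    nj <- colSums(attr(refit, "counts")[[v]])
    se <- sqrt(tr * (1 - tr) / rep(pmax(nj, 1), each = nrow(tr)))
    ok <- rep(nj >= 1000, each = nrow(tr))
    expect_lt(max((abs(est - tr) / pmax(se, 1e-6))[ok]), 4.5)
  }
})

test_that("published table fixtures match the published baseline counts", {
  counts <- table1_counts()
  expect_equal(sum(counts$normal[counts$variable == "Sex"]), 4110)
  expect_equal(sum(counts$hhcy[counts$variable == "Sex"]), 8175)
  tabs <- table1_tables()
  expect_length(tabs, 20L)
  for (tab in tabs) expect_equal(tab$total, 12285)
  expect_equal(unname(tabs$Exercise$counts),
               rbind(c(2420, 4752), c(1690, 3423)))
  expect_equal(unname(tabs$Sex$counts),
               rbind(c(1195, 4011), c(2915, 4164)))
})

test_that("the generating network matches the published marginals", {
  truth <- hhcy_truth_network()
  expect_equal(marginal(truth$network, "Hcy")$prob[2], 8175 / 12285,
               tolerance = 1e-9)
  counts <- table1_counts()
  for (v in c("Sex", "Age", "SBP", "FPG", "Smoking", "Diet", "Income")) {
    d <- counts[counts$variable == v, ]
    want <- (d$normal + d$hhcy)[match(truth$network$states[[v]], d$state)]
    expect_equal(marginal(truth$network, v)$prob, want / sum(want),
                 tolerance = 1e-9)
  }
  expect_equal(nrow(dag_edges(truth$core_dag)), 14L)
})

test_that("small populations carry all variables; marginals track the target", {
  tiny <- make_hhcy_population(100, seed = 2)
  expect_equal(dim(tiny$data), c(100L, 21L))
  pop <- pop50k()
  expect_lt(abs(mean(pop$data$Hcy == "HHcy") - 0.665), 0.01)
})

test_that("screening on a large sample reproduces the qualitative pattern", {
  d <- make_hhcy_population(200000, seed = 9)$data
  s <- screen_variables(d, "Hcy")
  expect_setequal(s$variable[!s$selected], c("Exercise", "ACR"))
})
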