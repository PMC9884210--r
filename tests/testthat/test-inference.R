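test_that("marginals and posteriors equal full joint enumeration", {
  for (seed in 1:30) {
    bn <- random_bn(4, max_states = 3, seed = seed)
    v <- bn$dag$nodes[1 + seed %% 4]
    expect_equal(marginal(bn, v)$prob, oracle_posterior(bn, v),
                 tolerance = 1e-10)
    # single- and double-variable evidence
    ev_var <- setdiff(bn$dag$nodes, v)[1]
    ev <- setNames(list(bn$states[[ev_var]][1]), ev_var)
    expect_equal(posterior(bn, v, ev)$prob, oracle_posterior(bn, v, ev),
                 tolerance = 1e-10)
    ev2_var <- setdiff(bn$dag$nodes, c(v, ev_var))[1]
    ev2 <- c(ev, setNames(list(bn$states[[ev2_var]][2]), ev2_var))
    expect_equal(posterior(bn, v, ev2)$prob, oracle_posterior(bn, v, ev2),
                 tolerance = 1e-10)
  }
  for (seed in 31:50) {
    bn <- random_bn(5, max_states = 3, seed = seed)
    v <- bn$dag$nodes[1 + seed %% 5]
    ev_var <- setdiff(bn$dag$nodes, v)[2]
    ev <- setNames(list(bn$states[[ev_var]][1]), ev_var)
    expect_equal(posterior(bn, v, ev)$prob, oracle_posterior(bn, v, ev),
                 tolerance = 1e-10)
  }
})

test_that("answers are invariant to the elimination order", {
  bn <- random_bn(5, max_states = 3, seed = 101)
  v <- bn$dag$nodes[3]
  ev <- setNames(list(bn$states[[bn$dag$nodes[1]]][1]), bn$dag$nodes[1])
  ref <- posterior(bn, v, ev)$prob
  others <- setdiff(bn$dag$nodes, c(v, names(ev)))
  set.seed(101)
  for (rep in 1:5) {
    ord <- sample(others)
    expect_equal(posterior(bn, v, ev, order = ord)$prob, ref,
                 tolerance = 1e-12)
  }
})

test_that("structural independence and degenerate queries behave exactly", {
  # deterministic chain with identity CPTs: marginal equals the root prior
  g <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  st <- list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y"))
  ident <- diag(2)
  bn <- bayesian_network(g, st, list(A = c(0.3, 0.7), B = ident, C = ident))
  expect_equal(marginal(bn, "C")$prob, c(0.3, 0.7), tolerance = 1e-12)
  # evidence d-separated from the query leaves the prior unchanged
  g2 <- dag(c("A", "B"))
  bn2 <- bayesian_network(g2, st[c("A", "B")],
                          list(A = c(0.3, 0.7), B = c(0.6, 0.4)))
  expect_equal(posterior(bn2, "A", evidence(B = "x"))$prob,
               marginal(bn2, "A")$prob, tolerance = 1e-12)
  # evidence on the query itself is a point mass
  expect_equal(posterior(bn, "B", evidence(B = "y"))$prob, c(0, 1))
  # impossible evidence is an error naming the assignment
  expect_error(posterior(bn, "A", evidence(B = "x", C = "y")),
               "zero-probability")
  expect_error(marginal(bn, "Nope"), "unknown")
})

test_that("chained evidence equals joint evidence", {
  bn <- random_bn(5, max_states = 3, seed = 77)
  nodes <- bn$dag$nodes
  e1 <- setNames(list(bn$states[[nodes[2]]][1]), nodes[2])
  e2 <- setNames(list(bn$states[[nodes[4]]][2]), nodes[4])
  expect_equal(posterior(bn, nodes[1], c(e1, e2))$prob,
               posterior(bn, nodes[1], c(e2, e1))$prob, tolerance = 1e-12)
})

test_that("sequential risk reasoning raises the outcome probability", {
  bn <- hhcy_truth_network()$network
  prior <- marginal(bn, "Hcy")$prob[2]
  p1 <- posterior(bn, "Hcy", evidence(SBP = "High"))$prob[2]
  p2 <- posterior(bn, "Hcy", evidence(SBP = "High", Age = "71-91"))$prob[2]
  p3 <- posterior(bn, "Hcy", evidence(SBP = "High", Age = "71-91",
                                      MCR = "Abnormal"))$prob[2]
  expect_true(prior < p1 && p1 < p2 && p2 < p3)
  # accumulating evidence step by step is the same query
  e <- evidence(SBP = "High")
  e <- c(e, evidence(Age = "71-91"))
  expect_equal(posterior(bn, "Hcy", e)$prob[2], p2, tolerance = 1e-12)
})

test_that("per-row predictions equal Bayes' rule by enumeration", {
  bn <- random_bn(3, max_states = 3, seed = 55)
  d <- sample_bn(bn, 60, seed = 56)
  tgt <- bn$dag$nodes[2]
  pp <- predict_proba(bn, tgt, d)
  for (i in 1:nrow(d)) {
    ev <- purrr::map(setNames(setdiff(names(d), tgt),
                              setdiff(names(d), tgt)),
                     function(v) as.character(d[[v]][i]))
    expect_equal(unlist(pp[i, ], use.names = FALSE),
                 oracle_posterior(bn, tgt, ev), tolerance = 1e-10)
  }
  # parentless, childless target: constant prediction at the prior
  g <- dag(c("A", "B"))
  bn2 <- bayesian_network(g, list(A = c("x", "y"), B = c("x", "y")),
                          list(A = c(0.25, 0.75), B = c(0.5, 0.5)))
  pp2 <- predict_proba(bn2, "A", tibble::tibble(
    B = factor(c("x", "y", "x"), c("x", "y"))))
  expect_true(all(pp2$y == 0.75))
})

test_that("predictions average out to the target's marginal", {
  bn <- random_bn(4, max_states = 2, seed = 91)
  d <- sample_bn(bn, 50000, seed = 92)
  tgt <- bn$dag$nodes[1]
  pp <- predict_proba(bn, tgt, d)
  expect_equal(colMeans(pp), setNames(marginal(bn, tgt)$prob,
                                      bn$states[[tgt]]),
               tolerance = 0.01)
})

test_that("hard CPT zeros propagate exactly; impossible rows are rescored", {
  g <- dag(c("A", "B"), rbind(c("A", "B")))
  st <- list(A = c("x", "y"), B = c("x", "y"))
  # B = y is impossible under A = x
  bn <- bayesian_network(g, st, list(A = c(0.5, 0.5),
                                     B = rbind(c(1, 0.2), c(0, 0.8))))
  d2 <- tibble::tibble(B = factor(c("y", "x"), c("x", "y")))
  expect_silent(pp <- predict_proba(bn, "A", d2))
  expect_equal(pp$x[1], 0, tolerance = 1e-12)  # P(A=x | B=y) = 0
  # chain where a forced evidence row is impossible: A -> B -> C with
  # B copying A and C = y impossible under B = x; the row (A=x, C=y)
  # has probability zero, so prediction rescores with reduced evidence
  g3 <- dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  st3 <- list(A = c("x", "y"), B = c("x", "y"), C = c("x", "y"))
  bn3 <- bayesian_network(g3, st3, list(
    A = c(0.5, 0.5),
    B = rbind(c(1, 0), c(0, 1)),
    C = rbind(c(1, 0.5), c(0, 0.5))))
  dd <- tibble::tibble(A = factor("x", c("x", "y")),
                       C = factor("y", c("x", "y")))
  expect_warning(pp3 <- predict_proba(bn3, "B", dd), "zero-probability")
  # after dropping the conflicting assignment, P(B | C = y) = (0, 1)
  expect_equal(unlist(pp3[1, ], use.names = FALSE), c(0, 1),
               tolerance = 1e-12)
})
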