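test_that("the outcome prior from the published group sizes is 0.665", {
  d <- tibble::tibble(
    Hcy = factor(rep(c("Normal", "HHcy"), times = c(4110, 8175)),
                 c("Normal", "HHcy")))
  bn <- fit_mle(d, dag("Hcy"))
  expect_equal(round(as.numeric(bn$cpts$Hcy)[2], 3), 0.665)
})

test_that("conditional frequencies match hand counts on a 2-node toy", {
  d <- tibble::tibble(
    X = factor(c("a", "a", "a", "b", "b", "b", "b", "a"), c("a", "b")),
    Y = factor(c("u", "u", "v", "v", "v", "u", "v", "u"), c("u", "v")))
  bn <- fit_mle(d, dag(c("X", "Y"), rbind(c("X", "Y"))))
  cpt <- bn$cpts$Y
  expect_equal(cpt["u", "a"], 3 / 4)     # X=a: Y u,u,v,u
  expect_equal(cpt["v", "b"], 3 / 4)     # X=b: Y v,v,u,v
  expect_equal(as.numeric(bn$cpts$X), c(0.5, 0.5))
})

test_that("unobserved parent configurations fall back to uniform rows", {
  d <- tibble::tibble(
    X = factor(c("a", "a", "a"), c("a", "b")),   # X=b never observed
    Y = factor(c("u", "v", "u"), c("u", "v")))
  bn <- fit_mle(d, dag(c("X", "Y"), rbind(c("X", "Y"))))
  expect_equal(unname(bn$cpts$Y[, "b"]), c(0.5, 0.5))
  sm <- fit_mle(d, dag(c("X", "Y"), rbind(c("X", "Y"))), pseudocount = 1)
  expect_equal(unname(sm$cpts$Y[, "b"]), c(0.5, 0.5))
  expect_equal(unname(sm$cpts$Y[, "a"]), c(3, 2) / 5)  # Laplace on counts 2,1
})

test_that("every CPT row is a distribution within 1e-12", {
  pop <- pop20k()
  bn <- fit_mle(pop$data[pop$core_nodes][1:5000, ], pop$core_dag)
  for (v in bn$dag$nodes) {
    m <- matrix(bn$cpts[[v]], nrow = length(bn$states[[v]]))
    expect_true(all(abs(colSums(m) - 1) < 1e-12))
    expect_true(all(m >= 0))
  }
  # implied joint sums to one on a small network (enumeration)
  small <- fit_mle(pop$data[c("Sex", "Smoking", "Hcy")][1:3000, ],
                   dag(c("Sex", "Smoking", "Hcy"),
                       rbind(c("Sex", "Smoking"), c("Sex", "Hcy"))))
  expect_equal(sum(brute_joint(small)$prob), 1, tolerance = 1e-12)
})

test_that("MLE parameters maximise the training log-likelihood", {
  d <- vstructure_dataset(2000, seed = 9)
  g <- dag(names(d), rbind(c("X", "Z"), c("Y", "Z")))
  bn <- fit_mle(d, g)
  ll <- bn_loglik(bn, d)
  set.seed(9)
  for (rep in 1:20) {
    pert <- bn
    v <- sample(g$nodes, 1)
    m <- matrix(pert$cpts[[v]], nrow = length(pert$states[[v]]))
    m <- m + matrix(runif(length(m), 0, 0.15), nrow = nrow(m))
    m <- sweep(m, 2, colSums(m), "/")
    pert$cpts[[v]] <- array(m, dim = dim(pert$cpts[[v]]) %||% length(m),
                            dimnames = dimnames(pert$cpts[[v]]))
    expect_lte(bn_loglik(pert, d), ll + 1e-9)
  }
})

test_that("JSON round-trip preserves structure, parameters and queries", {
  pop <- pop20k()
  bn <- fit_mle(pop$data[pop$core_nodes][1:4000, ], pop$core_dag)
  f <- withr::local_tempfile(fileext = ".json")
  write_bn(bn, f)
  back <- read_bn(f)
  expect_identical(back$dag$adj, bn$dag$adj)
  expect_equal(back$cpts, bn$cpts, tolerance = 1e-15)
  ev <- evidence(SBP = "High", Age = "71-91")
  expect_equal(posterior(back, "Hcy", ev)$prob,
               posterior(bn, "Hcy", ev)$prob, tolerance = 1e-12)
})

test_that("refit on sampled data recovers well-supported CPT entries", {
  # fixture designed so every parent configuration has expected count
  # >= 20,000 at n = 100,000: the 0.02 bound is then ~7 binomial SEs
  g <- dag(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
  states <- list(X = c("a", "b"), Y = c("a", "b"), Z = c("a", "b", "c"))
  cpts <- list(X = c(0.45, 0.55),
               Y = rbind(c(0.7, 0.35), c(0.3, 0.65)),
               Z = rbind(c(0.5, 0.2), c(0.3, 0.5), c(0.2, 0.3)))
  bn <- bayesian_network(g, states, cpts)
  d <- sample_bn(bn, 100000, seed = 34)
  refit <- fit_mle(d, bn$dag)
  cnts <- attr(refit, "counts")
  for (v in bn$dag$nodes) {
    r <- length(bn$states[[v]])
    tr <- matrix(bn$cpts[[v]], nrow = r)
    est <- matrix(refit$cpts[[v]], nrow = r)
    nj <- colSums(cnts[[v]])
    ok <- nj >= 500
    expect_true(any(ok))
    expect_lt(max(abs(est[, ok] - tr[, ok])), 0.02)
  }
})
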