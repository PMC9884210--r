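#' Ancestral sampling from a Bayesian network
#'
#' Draws `n` subjects by sampling each node in topological order from its
#' CPT row given the already-sampled parents. Randomness comes from R's
#' default Mersenne-Twister generator; a given integer `seed` makes the
#' draw byte-reproducible.
#'
#' @param bn An `hcy_bn`.
#' @param n Number of subjects (>= 1).
#' @param seed Optional integer seed.
#' @return A coded tibble of factors, columns in network node order.
#' @export
sample_bn <- function(bn, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  codes <- list()
  for (v in topo_sort(bn$dag)) {
    pa <- dag_parents(bn$dag, v)
    r <- length(bn$states[[v]])
    pm <- matrix(bn$cpts[[v]], nrow = r)
    cfg <- rep_len(1L, n)
    stride <- 1L
    for (p in pa) {
      cfg <- cfg + (codes[[p]] - 1L) * stride
      stride <- stride * length(bn$states[[p]])
    }
    cum <- t(apply(pm, 2L, cumsum))       # q x r cumulative rows
    u <- runif(n)
    codes[[v]] <- pmin(1L + rowSums(u > cum[cfg, , drop = FALSE]), r)
  }
  tibble::as_tibble(purrr::map(setNames(bn$dag$nodes, bn$dag$nodes),
                               function(v) {
                                 factor(bn$states[[v]][codes[[v]]],
                                        levels = bn$states[[v]])
                               }))
}

# ---- ground-truth network construction ---------------------------------

# Exact joint over `vars` (a named probability vector over their
# column-major configuration grid, first variable fastest) by enumerating
# the ancestral closure of `vars` in the partially built network.
joint_config <- function(built, vars) {
  closure <- vars
  repeat {
    grown <- unique(c(closure, unlist(built$parents[closure])))
    if (length(grown) == length(closure)) break
    closure <- grown
  }
  grid <- expand.grid(purrr::map(built$states[closure],
                                 function(s) seq_along(s)),
                      KEEP.OUT.ATTRS = FALSE)
  w <- rep_len(1, nrow(grid))
  for (v in closure) {
    pa <- built$parents[[v]]
    pm <- matrix(built$cpts[[v]], nrow = length(built$states[[v]]))
    cfg <- rep_len(1L, nrow(grid))
    stride <- 1L
    for (p in pa) {
      cfg <- cfg + (grid[[p]] - 1L) * stride
      stride <- stride * length(built$states[[p]])
    }
    w <- w * pm[cbind(grid[[v]], cfg)]
  }
  cfg <- rep_len(1L, nrow(grid))
  stride <- 1L
  for (p in vars) {
    cfg <- cfg + (grid[[p]] - 1L) * stride
    stride <- stride * length(built$states[[p]])
  }
  as.vector(rowsum(w, cfg))
}

# Linear predictor over the parent configuration grid from 0-based scores.
grid_eta <- function(built, parents, coefs) {
  grid <- expand.grid(purrr::map(built$states[parents],
                                 function(s) seq_along(s)),
                      KEEP.OUT.ATTRS = FALSE)
  eta <- rep_len(0, nrow(grid))
  for (j in seq_along(parents)) {
    eta <- eta + coefs[[j]] * (grid[[parents[j]]] - 1L)
  }
  eta
}

add_root <- function(built, node, marg) {
  built$parents[[node]] <- character(0)
  built$cpts[[node]] <- marg / sum(marg)
  built
}

# Binary child with logistic CPT; the intercept is solved so the implied
# marginal of the second state matches `target2` exactly.
add_logistic <- function(built, node, parents, coefs, target2) {
  w <- joint_config(built, parents)
  eta <- grid_eta(built, parents, coefs)
  b0 <- stats::uniroot(function(b) sum(w * stats::plogis(eta + b)) - target2,
                       c(-30, 30), tol = 1e-12)$root
  p2 <- stats::plogis(eta + b0)
  built$parents[[node]] <- parents
  built$cpts[[node]] <- rbind(1 - p2, p2)
  built
}

# Ordinal child with proportional-odds CPT: P(Y >= k | pa) =
# plogis(eta - t_k); each threshold is solved to match the target marginal.
add_cumulative <- function(built, node, parents, coefs, target_marg) {
  w <- joint_config(built, parents)
  eta <- grid_eta(built, parents, coefs)
  k_states <- length(target_marg)
  target_marg <- target_marg / sum(target_marg)
  cum <- matrix(0, k_states + 1L, length(eta))
  cum[1L, ] <- 1
  for (k in 2:k_states) {
    tk <- stats::uniroot(function(t) {
      sum(w * stats::plogis(eta - t)) - sum(target_marg[k:k_states])
    }, c(-40, 40), tol = 1e-12)$root
    cum[k, ] <- stats::plogis(eta - tk)
  }
  built$parents[[node]] <- parents
  built$cpts[[node]] <- cum[1:k_states, , drop = FALSE] -
    cum[2:(k_states + 1L), , drop = FALSE]
  built
}

#' Ground-truth network behind the synthetic population
#'
#' A 21-node discrete Bayesian network over the full clinical schema,
#' calibrated so that every variable's marginal matches the published
#' baseline table exactly. Its core is the 10-variable risk-factor
#' subnetwork (the nine multivariate risk factors plus the homocysteine
#' outcome, 14 directed edges): homocysteine status depends directly on
#' all nine (with age, sex, MCR, FPG, diet and SBP carrying the strong
#' effects and smoking, GHb and BMI weak ones), while SBP <- {Age, BMI},
#' FPG <- {MCR, GHb} and Smoking <- Sex provide the indirect pathways.
#' The remaining variables are downstream correlates (so univariate
#' screening finds them associated with the outcome) except Exercise and
#' ACR, which are independent roots. Effect sizes are fixed constants on
#' the logit scale, chosen once from the published univariate and
#' multivariate effect magnitudes.
#'
#' @return A list: `network` (`hcy_bn` over all 21 variables),
#'   `core_nodes` (the 10 risk-analysis variables), `core_dag` (the
#'   induced ground-truth structure over them, the recovery target).
#' @export
hhcy_truth_network <- function() {
  tc <- table1_counts()
  schema <- hhcy_schema()
  states <- purrr::map(schema, "states")
  marg <- function(v) {
    d <- tc[tc$variable == v, ]
    p <- (d$normal + d$hhcy)[match(states[[v]], d$state)]
    p / sum(p)
  }
  built <- list(parents = list(), cpts = list(), states = states)
  for (v in c("Sex", "Age", "BMI", "MCR", "GHb", "Diet")) {
    built <- add_root(built, v, marg(v))
  }
  built <- add_root(built, "Exercise", marg("Exercise"))
  built <- add_root(built, "ACR", marg("ACR"))
  built <- add_logistic(built, "Smoking", "Sex", -3.3, marg("Smoking")[2L])
  built <- add_cumulative(built, "SBP", c("Age", "BMI"), c(0.45, 0.50),
                          marg("SBP"))
  built <- add_cumulative(built, "FPG", c("MCR", "GHb"), c(0.5, 2.2),
                          marg("FPG"))
  built <- add_logistic(built, "Hcy",
                        c("Age", "Sex", "MCR", "FPG", "Diet", "SBP",
                          "Smoking", "GHb", "BMI"),
                        c(0.35, -0.85, 0.45, -0.30, -0.55, 0.30,
                          0.17, -0.35, 0.093),
                        8175 / 12285)
  built <- add_cumulative(built, "Education", "Age", -0.6,
                          marg("Education"))
  built <- add_cumulative(built, "Income", c("Education", "Age"),
                          c(0.6, -0.35), marg("Income"))
  built <- add_logistic(built, "TG", c("BMI", "Diet"), c(0.25, 0.55),
                        marg("TG")[2L])
  built <- add_logistic(built, "TC", c("BMI", "Diet"), c(0.2, 0.85),
                        marg("TC")[2L])
  built <- add_logistic(built, "LDL", c("TC", "Age", "SBP"),
                        c(2.2, 0.45, 0.4), marg("LDL")[2L])
  built <- add_logistic(built, "HDL", c("Sex", "BMI"), c(1.1, -0.45),
                        marg("HDL")[2L])
  built <- add_cumulative(built, "DBP", "SBP", 1.1, marg("DBP"))
  built <- add_cumulative(built, "Alcohol", c("Sex", "Smoking"),
                          c(-1.5, 0.8), marg("Alcohol"))
  built <- add_cumulative(built, "Salt", "Diet", 0.5, marg("Salt"))
  nodes <- names(schema)
  edges <- purrr::map_dfr(nodes, function(v) {
    pa <- built$parents[[v]]
    if (length(pa) == 0L) return(NULL)
    tibble::tibble(parent = pa, child = v)
  })
  g <- dag(nodes, edges)
  # permute CPT parent dimensions from declared order to structure order
  cpts <- purrr::map(setNames(nodes, nodes), function(v) {
    pa <- built$parents[[v]]
    if (length(pa) < 2L) return(built$cpts[[v]])
    arr <- array(built$cpts[[v]],
                 dim = c(length(states[[v]]), lengths(states[pa])))
    aperm(arr, c(1L, 1L + match(dag_parents(g, v), pa)))
  })
  network <- bayesian_network(g, states[nodes], cpts)
  core_nodes <- c("Sex", "Age", "BMI", "MCR", "GHb", "Diet", "Smoking",
                  "SBP", "FPG", "Hcy")
  core_edges <- dplyr::filter(edges, .data$parent %in% core_nodes,
                              .data$child %in% core_nodes)
  list(network = network,
       core_nodes = core_nodes,
       core_dag = dag(core_nodes, core_edges))
}

#' Simulate a study population with known structure
#'
#' Samples `n` subjects from [hhcy_truth_network()], the calibrated
#' ground-truth network, so that every pipeline stage can be validated
#' against a known data-generating process: marginals match the published
#' baseline table, univariate screening finds Exercise and ACR (and only
#' those) unassociated with homocysteine status, stepwise logistic
#' selection recovers the nine multivariate risk factors, and structure
#' learning can be scored against the generating core DAG.
#'
#' @param n Number of subjects (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @return A list: `data` (coded tibble, 21 columns), `network` (the
#'   generating `hcy_bn`), `core_nodes`, `core_dag` (recovery target over
#'   the 10 risk-analysis variables), `n`, `seed`.
#' @export
make_hhcy_population <- function(n, seed = NULL) {
  stopifnot(n >= 100)
  truth <- hhcy_truth_network()
  data <- sample_bn(truth$network, n, seed = seed)
  list(data = data, network = truth$network,
       core_nodes = truth$core_nodes, core_dag = truth$core_dag,
       n = n, seed = seed)
}
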