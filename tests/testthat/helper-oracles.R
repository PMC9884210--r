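# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (variable elimination, cached family
# scores, rank-based AUC) so agreement is evidence, not tautology.

# Full joint distribution of a network by direct enumeration: a data frame
# of every configuration with its probability, built with plain loops.
brute_joint <- function(bn) {
  nodes <- bn$dag$nodes
  grid <- expand.grid(lapply(bn$states[nodes], seq_along),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- nodes
  prob <- rep(1, nrow(grid))
  for (v in nodes) {
    pa <- dag_parents(bn$dag, v)
    cpt <- bn$cpts[[v]]
    for (i in seq_len(nrow(grid))) {
      idx <- c(grid[[v]][i], unlist(grid[i, pa], use.names = FALSE))
      prob[i] <- prob[i] * cpt[matrix(idx, nrow = 1)]
    }
  }
  cbind(grid, prob = prob)
}

# Oracle posterior P(var | evidence) from the enumerated joint.
oracle_posterior <- function(bn, var, evid = list()) {
  j <- brute_joint(bn)
  keep <- rep(TRUE, nrow(j))
  for (e in names(evid)) {
    keep <- keep & j[[e]] == match(evid[[e]], bn$states[[e]])
  }
  j <- j[keep, , drop = FALSE]
  p <- vapply(seq_along(bn$states[[var]]), function(k) {
    sum(j$prob[j[[var]] == k])
  }, numeric(1))
  p / sum(p)
}

# Random discrete network: random DAG (edge probability `p_edge` over a
# random topological order) with independent uniform-normalised CPT rows.
random_bn <- function(n_nodes, max_states = 3L, p_edge = 0.5, seed = 1L) {
  set.seed(seed)
  nodes <- paste0("V", seq_len(n_nodes))
  ord <- sample(nodes)
  edges <- NULL
  for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (i < j && runif(1) < p_edge) {
      edges <- rbind(edges, c(ord[i], ord[j]))
    }
  }
  g <- dag(nodes, edges)
  states <- lapply(setNames(nodes, nodes), function(v) {
    k <- if (max_states <= 2L) 2L else sample(2:max_states, 1)
    paste0("s", seq_len(k))
  })
  cpts <- lapply(setNames(nodes, nodes), function(v) {
    pa <- dag_parents(g, v)
    r <- length(states[[v]])
    q <- prod(vapply(states[pa], length, 1L), 1L)
    m <- matrix(runif(r * q, min = 0.05), nrow = r)
    sweep(m, 2, colSums(m), "/")
  })
  bayesian_network(g, states, cpts)
}

# Every DAG over the given nodes, as a list of 2-column edge matrices,
# by filtering all directed-edge subsets for acyclicity (brute force).
all_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- which(matrix(TRUE, p, p) & !diag(p), arr.ind = TRUE)
  m <- nrow(pairs)
  acyclic <- function(adj) {
    # repeated leaf-stripping
    left <- seq_len(p)
    repeat {
      if (length(left) == 0L) return(TRUE)
      deg <- colSums(adj[left, left, drop = FALSE])
      src <- left[deg == 0]
      if (length(src) == 0L) return(FALSE)
      left <- setdiff(left, src)
    }
  }
  out <- list()
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
    adj <- matrix(FALSE, p, p)
    adj[pairs[sel, , drop = FALSE]] <- TRUE
    if (any(adj & t(adj))) next
    if (!acyclic(adj)) next
    idx <- which(adj, arr.ind = TRUE)
    out[[length(out) + 1L]] <- cbind(nodes[idx[, 1]], nodes[idx[, 2]])
  }
  out
}

# Exhaustive-enumeration optimum of the network score over all DAGs
# (memoised per family to keep 4-node enumeration quick).
exhaustive_best_score <- function(dataset, nodes = names(dataset),
                                  score = "bic") {
  memo <- new.env(parent = emptyenv())
  fam <- function(v, pa) {
    key <- paste(v, paste(sort(pa), collapse = ","), sep = "|")
    if (is.null(memo[[key]])) {
      memo[[key]] <- family_score(dataset, v, pa, score = score)
    }
    memo[[key]]
  }
  best <- -Inf
  for (edges in all_dags(nodes)) {
    g <- dag(nodes, if (nrow(edges) > 0) edges)
    s <- sum(vapply(nodes, function(v) fam(v, dag_parents(g, v)),
                    numeric(1)))
    if (s > best) best <- s
  }
  best
}

# Pearson chi-square by explicit O/E loops, p-value by numerical
# integration of the chi-square density.
chisq_oracle <- function(m, correct = FALSE) {
  n <- sum(m)
  stat <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    e <- sum(m[i, ]) * sum(m[, j]) / n
    d <- abs(m[i, j] - e)
    if (correct) d <- max(0, d - 0.5)
    stat <- stat + d^2 / e
  }
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  p <- if (stat == 0) 1 else {
    stats::integrate(function(x) stats::dchisq(x, df), stat, Inf,
                     rel.tol = 1e-12)$value
  }
  list(stat = stat, df = df, p = p)
}

# O(n^2) pair-counting AUC, ties counted one half.
auc_oracle <- function(scores, pos) {
  s1 <- scores[pos]
  s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(s1) * length(s0))
}

# Planted-local-optimum dataset: C is a noisy XOR of the independent coins
# A and B (so no single edge into C improves the score from the empty
# graph), plus a strong pendant edge C -> D that greedy search does find.
xor_dataset <- function(n = 8000, seed = 99, flip = 0.1) {
  set.seed(seed)
  a <- stats::rbinom(n, 1, 0.5)
  b <- stats::rbinom(n, 1, 0.5)
  c <- ifelse(runif(n) < 1 - flip, as.integer(xor(a, b)),
              1L - as.integer(xor(a, b)))
  d <- ifelse(runif(n) < 1 - flip, c, 1L - c)
  tibble::tibble(A = factor(a, 0:1), B = factor(b, 0:1),
                 C = factor(c, 0:1), D = factor(d, 0:1))
}

# Small categorical dataset sampled from independent uniform variables.
independent_dataset <- function(n, k_vars, n_states = 2L, seed = 1L) {
  set.seed(seed)
  tibble::as_tibble(lapply(setNames(seq_len(k_vars),
                                    paste0("X", seq_len(k_vars))),
                           function(i) {
                             factor(sample(paste0("s", seq_len(n_states)),
                                           n, replace = TRUE))
                           }))
}
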