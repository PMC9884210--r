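# Prepared scoring data: integer codes and level counts, computed once per
# search so family scores are O(n) tabulations.
score_data <- function(dataset, nodes = names(dataset)) {
  codes <- vapply(nodes, function(v) {
    col <- dataset[[v]]
    if (is.null(col)) abort(sprintf("no variable '%s'", v))
    as.integer(col)
  }, integer(nrow(dataset)))
  if (nrow(dataset) == 0L) abort("dataset is empty")
  nlev <- vapply(nodes, function(v) nlevels(dataset[[v]]), integer(1))
  list(codes = codes, nlev = nlev, nodes = nodes, n = nrow(dataset))
}

# Decomposable family score from prepared data. BIC (natural log):
#   sum_jk N_jk ln(N_jk / N_j) - (ln n / 2) (r - 1) q,  0 ln 0 = 0,
# r = node states, q = parent configurations. AIC swaps the penalty for
# (r - 1) q; "loglik" is the unpenalised term.
family_score_sd <- function(sd, node, parents, score = "bic") {
  r <- sd$nlev[[node]]
  x <- sd$codes[, node]
  if (length(parents) == 0L) {
    njk <- tabulate(x, nbins = r)
    nj <- rep_len(sd$n, r)
    q <- 1L
  } else {
    q <- prod(sd$nlev[parents])
    cfg <- rep_len(1L, sd$n)
    stride <- 1L
    for (p in parents) {
      cfg <- cfg + (sd$codes[, p] - 1L) * stride
      stride <- stride * sd$nlev[[p]]
    }
    njk <- tabulate(cfg + (x - 1L) * q, nbins = q * r)
    nj <- rep_len(tabulate(cfg, nbins = q), r * q)  # recycled per state block
    njk <- matrix(njk, nrow = q)
    nj <- matrix(nj, nrow = q)
  }
  pos <- njk > 0
  ll <- sum(njk[pos] * log(njk[pos] / nj[pos]))
  pen <- switch(score,
    bic = log(sd$n) / 2 * (r - 1) * q,
    aic = (r - 1) * q,
    loglik = 0,
    abort(sprintf("unknown score '%s'", score)))
  ll - pen
}

#' Decomposable network score of one node family
#'
#' The local score of `node` with parent set `parents`: the multinomial
#' log-likelihood of the node's conditional frequencies, minus (for BIC,
#' the default) a complexity penalty of (ln n / 2) x (r - 1) x q free
#' parameters, where r is the node's state count and q the number of
#' parent configurations. The total score of a structure is the sum of its
#' family scores.
#'
#' @param dataset Coded tibble of factors.
#' @param node Node name.
#' @param parents Character vector of parent names (may be empty); must not
#'   contain `node`.
#' @param score `"bic"` (default), `"aic"` or `"loglik"`.
#' @return The family score (a scalar; larger is better).
#' @export
family_score <- function(dataset, node, parents = character(0),
                         score = "bic") {
  if (node %in% parents) abort("a node cannot be its own parent")
  sd <- score_data(dataset, unique(c(node, parents)))
  family_score_sd(sd, node, parents, score)
}

#' Total network score of a structure
#'
#' @param dataset Coded tibble of factors.
#' @param x An [dag()] whose nodes all appear in `dataset`.
#' @param score `"bic"`, `"aic"` or `"loglik"`.
#' @return Sum of family scores over all nodes.
#' @export
bn_score <- function(dataset, x, score = "bic") {
  sd <- score_data(dataset, x$nodes)
  sum(vapply(x$nodes, function(v) {
    family_score_sd(sd, v, dag_parents(x, v), score)
  }, numeric(1)))
}

# Memoising family-score cache over one prepared dataset.
make_score_cache <- function(sd, score) {
  cache <- new.env(parent = emptyenv())
  function(node, parents) {
    key <- paste0(node, "|", paste(sort(parents), collapse = ","))
    val <- cache[[key]]
    if (is.null(val)) {
      val <- family_score_sd(sd, node, parents, score)
      cache[[key]] <- val
    }
    val
  }
}
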