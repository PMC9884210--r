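#' Construct a discrete Bayesian network from explicit tables
#'
#' A network couples a [dag()] with one conditional probability table per
#' node. Each CPT is a numeric array whose first dimension runs over the
#' node's states and whose remaining dimensions run over its parents'
#' states in the structure's declared parent order; every conditional
#' distribution (column over the first dimension) must sum to one.
#'
#' @param x An `hcy_dag`.
#' @param states Named list: one character vector of state labels per node.
#' @param cpts Named list: one probability array per node, dimensions
#'   (node states, parent1 states, parent2 states, ...). A parentless node
#'   takes a plain probability vector.
#' @return An object of class `hcy_bn`.
#' @export
bayesian_network <- function(x, states, cpts) {
  stopifnot(inherits(x, "hcy_dag"))
  if (!setequal(names(states), x$nodes) || !setequal(names(cpts), x$nodes)) {
    abort("states and cpts must name every node exactly")
  }
  cpts_out <- list()
  for (v in x$nodes) {
    pa <- dag_parents(x, v)
    r <- length(states[[v]])
    q <- if (length(pa) == 0L) 1L else prod(lengths(states[pa]))
    tab <- array(as.numeric(cpts[[v]]), dim = c(r, q))
    if (length(tab) != r * q) {
      abort(sprintf("CPT for '%s' has wrong size (need %d x %d)", v, r, q))
    }
    if (any(tab < 0)) abort(sprintf("negative probability in CPT '%s'", v))
    sums <- colSums(tab)
    if (any(abs(sums - 1) > 1e-6)) {
      abort(sprintf("CPT rows for '%s' do not sum to 1", v))
    }
    tab <- sweep(tab, 2L, sums, "/")       # exact renormalisation
    dims <- c(r, if (length(pa)) lengths(states[pa]))
    cpts_out[[v]] <- array(tab, dim = dims,
                           dimnames = c(list(states[[v]]),
                                        if (length(pa)) states[pa]))
  }
  structure(list(dag = x, states = states[x$nodes], cpts = cpts_out[x$nodes]),
            class = "hcy_bn")
}

#' @export
print.hcy_bn <- function(x, ...) {
  cat(sprintf("<hcy_bn> %d nodes, %d edges, %d free parameters\n",
              length(x$dag$nodes), nrow(dag_edges(x$dag)), n_params(x)))
  invisible(x)
}

n_params <- function(bn) {
  sum(vapply(bn$dag$nodes, function(v) {
    d <- dim(bn$cpts[[v]]) %||% length(bn$cpts[[v]])
    (d[1L] - 1L) * prod(d[-1L], 1L)
  }, numeric(1)))
}

#' Maximum-likelihood CPT estimation
#'
#' Estimates every node's conditional probability table as conditional
#' relative frequencies: P(x | pa) = (N(x, pa) + c) / (N(pa) + c r) for
#' pseudocount c. With the default c = 0 this is the pure maximum
#' likelihood estimate; a parent configuration never observed yields a
#' uniform fallback row.
#'
#' @param dataset Coded tibble of factors covering all structure nodes.
#' @param x An [dag()].
#' @param pseudocount Non-negative smoothing count added to every cell.
#' @return An `hcy_bn` carrying the fitted tables and the underlying
#'   counts (attribute `counts`: per node, an (r x q) count matrix).
#' @export
fit_mle <- function(dataset, x, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  sd <- score_data(dataset, x$nodes)
  states <- purrr::map(setNames(x$nodes, x$nodes),
                       function(v) levels(dataset[[v]]))
  cpts <- list()
  counts <- list()
  for (v in x$nodes) {
    pa <- dag_parents(x, v)
    r <- sd$nlev[[v]]
    if (length(pa) == 0L) {
      njk <- matrix(tabulate(sd$codes[, v], nbins = r), nrow = r)
    } else {
      q <- prod(sd$nlev[pa])
      cfg <- rep_len(1L, sd$n)
      stride <- 1L
      for (p in pa) {
        cfg <- cfg + (sd$codes[, p] - 1L) * stride
        stride <- stride * sd$nlev[[p]]
      }
      njk <- matrix(tabulate((cfg - 1L) * r + sd$codes[, v], nbins = q * r),
                    nrow = r)
    }
    nj <- colSums(njk)
    prob <- sweep(njk + pseudocount, 2L, nj + pseudocount * r, "/")
    empty <- nj + pseudocount * r == 0
    prob[, empty] <- 1 / r                # unobserved configuration fallback
    counts[[v]] <- njk
    cpts[[v]] <- prob
  }
  bn <- bayesian_network(x, states, cpts)
  attr(bn, "counts") <- counts
  bn
}

#' @describeIn fit_mle Long-format CPT tibble: one row per (node, parent
#'   configuration, state) with its probability.
#' @param x An `hcy_bn` object (for the methods).
#' @param ... Unused.
#' @method tidy hcy_bn
#' @export
tidy.hcy_bn <- function(x, ...) {
  purrr::map_dfr(x$dag$nodes, function(v) {
    pa <- dag_parents(x$dag, v)
    grid <- expand.grid(c(x$states[v], x$states[pa]),
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    names(grid) <- c("state", pa)
    tibble::tibble(node = v, state = grid$state,
                   parents = if (length(pa) == 0L) "" else
                     apply(grid[pa, drop = FALSE], 1L, function(row) {
                       paste(pa, row, sep = "=", collapse = ",")
                     }),
                   prob = as.vector(x$cpts[[v]]))
  })
}

#' @describeIn fit_mle One-row network summary (nodes, edges, parameters).
#' @method glance hcy_bn
#' @export
glance.hcy_bn <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$dag$nodes),
                 n_edges = nrow(dag_edges(x$dag)),
                 n_params = n_params(x))
}

#' Log-likelihood of a dataset under a network
#'
#' @param bn An `hcy_bn`.
#' @param dataset Coded tibble of factors.
#' @return Scalar log-likelihood (natural log); `-Inf` when some row has
#'   probability zero.
#' @export
bn_loglik <- function(bn, dataset) {
  sd <- score_data(dataset, bn$dag$nodes)
  total <- 0
  for (v in bn$dag$nodes) {
    pa <- dag_parents(bn$dag, v)
    tab <- matrix(bn$cpts[[v]], nrow = sd$nlev[[v]])
    cfg <- rep_len(1L, sd$n)
    stride <- 1L
    for (p in pa) {
      cfg <- cfg + (sd$codes[, p] - 1L) * stride
      stride <- stride * sd$nlev[[p]]
    }
    total <- total + sum(log(tab[cbind(sd$codes[, v], cfg)]))
  }
  total
}

#' Write a network to JSON
#'
#' Round-trip serialization: node order, state labels, edges and CPT
#' values are preserved exactly (probabilities at full precision).
#'
#' @param bn An `hcy_bn`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bn <- function(bn, path) {
  obj <- list(
    nodes = bn$dag$nodes,
    states = bn$states,
    edges = as.data.frame(dag_edges(bn$dag)),
    cpts = purrr::map(setNames(bn$dag$nodes, bn$dag$nodes), function(v) {
      list(parents = dag_parents(bn$dag, v),
           dim = dim(bn$cpts[[v]]),
           prob = as.vector(bn$cpts[[v]]))
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a network from JSON
#'
#' @param path File written by [write_bn()].
#' @return The reconstructed `hcy_bn`.
#' @export
read_bn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- obj$nodes
  edges <- if (length(obj$edges) && nrow(as.data.frame(obj$edges)) > 0L) {
    as.data.frame(obj$edges)
  }
  g <- dag(nodes, edges)
  states <- purrr::map(obj$states, as.character)[nodes]
  cpts <- purrr::map(setNames(nodes, nodes), function(v) {
    array(obj$cpts[[v]]$prob, dim = obj$cpts[[v]]$dim)
  })
  bayesian_network(g, states, cpts)
}
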