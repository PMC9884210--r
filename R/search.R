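# Score deltas for every legal move on the current graph, using the cached
# family scores; only the changed families are rescored.
move_deltas <- function(g, moves, fs) {
  vapply(seq_len(nrow(moves)), function(i) {
    u <- moves$parent[i]; v <- moves$child[i]
    pa_v <- dag_parents(g, v)
    switch(moves$kind[i],
      add = fs(v, c(pa_v, u)) - fs(v, pa_v),
      delete = fs(v, setdiff(pa_v, u)) - fs(v, pa_v),
      reverse = {
        pa_u <- dag_parents(g, u)
        (fs(v, setdiff(pa_v, u)) - fs(v, pa_v)) +
          (fs(u, c(pa_u, v)) - fs(u, pa_u))
      })
  }, numeric(1))
}

search_setup <- function(dataset, nodes, score) {
  sd <- score_data(dataset, nodes)
  fs <- make_score_cache(sd, score)
  g <- dag(nodes)
  s <- sum(vapply(nodes, function(v) fs(v, character(0)), numeric(1)))
  list(fs = fs, g = g, s = s)
}

trace_row <- function(iter, kind, parent, child, delta, score, best) {
  tibble::tibble(iteration = iter, kind = kind, parent = parent,
                 child = child, delta = delta, score = score,
                 best_score = best)
}

#' Greedy hill climbing over structures
#'
#' Starting from the empty graph, repeatedly applies the single-edge move
#' (addition, deletion or reversal) with the largest strictly positive
#' score improvement, stopping at a local optimum. Ties break on the
#' deterministic lexicographic move order of [dag_moves()].
#'
#' @param dataset Coded tibble of factors.
#' @param nodes Nodes to learn over (default: all dataset columns).
#' @param score `"bic"` (default), `"aic"` or `"loglik"`.
#' @param max_parents Parent-count bound per node.
#' @param blacklist,whitelist Optional edge constraints (see [dag_moves()]).
#' @param max_iter Iteration budget.
#' @return A list of class `hcy_search`: `dag`, `score`, `trace` (one row
#'   per accepted move, scores strictly increasing), `algorithm`.
#' @export
hill_climb <- function(dataset, nodes = names(dataset), score = "bic",
                       max_parents = Inf, blacklist = NULL,
                       whitelist = NULL, max_iter = 10000L) {
  st <- search_setup(dataset, nodes, score)
  g <- st$g; s <- st$s; fs <- st$fs
  eps <- 1e-9
  trace <- list()
  for (iter in seq_len(max_iter)) {
    moves <- dag_moves(g, max_parents, blacklist, whitelist)
    if (nrow(moves) == 0L) break
    deltas <- move_deltas(g, moves, fs)
    best <- which.max(deltas)
    if (deltas[best] <= eps) break
    g <- apply_move(g, moves$kind[best], moves$parent[best],
                    moves$child[best])
    s <- s + deltas[best]
    trace[[length(trace) + 1L]] <- trace_row(
      iter, moves$kind[best], moves$parent[best], moves$child[best],
      deltas[best], s, s)
  }
  structure(list(dag = g, score = s,
                 trace = dplyr::bind_rows(trace), algorithm = "hc",
                 score_type = score),
            class = "hcy_search")
}

#' Tabu search over structures
#'
#' Score-based local search with a tabu list, following the classic
#' six-step scheme: (1) start from the empty graph; (2) stop when the
#' convergence criterion is met (`max_nonimproving` consecutive iterations
#' without improving the best score, or `max_iter`); (3) enumerate the
#' single-edge neighbourhood; (4) aspiration: a tabu move is admissible
#' only when it would strictly beat the best score seen; (5) otherwise take
#' the best non-tabu move, even when it worsens the score, and push the
#' inverse move onto the tabu list for `tenure` iterations; (6) repeat.
#' The best-scoring structure visited is returned, so the best-score trace
#' is non-decreasing and the result is never worse than hill climbing from
#' the same start when given the budget to reach it.
#'
#' @inheritParams hill_climb
#' @param tenure Number of iterations an inverse move stays tabu
#'   (default 10).
#' @param max_nonimproving Convergence criterion: stop after this many
#'   consecutive iterations without a new best score (default 15).
#' @return A list of class `hcy_search`: `dag` (best visited), `score`,
#'   `trace` (per-iteration move, score, best score, tabu-list size),
#'   `algorithm`.
#' @export
tabu_search <- function(dataset, nodes = names(dataset), score = "bic",
                        tenure = 10L, max_nonimproving = 15L,
                        max_iter = 10000L, max_parents = Inf,
                        blacklist = NULL, whitelist = NULL) {
  stopifnot(tenure >= 0L, max_iter >= 1L, max_nonimproving >= 1L)
  st <- search_setup(dataset, nodes, score)
  g <- st$g; s <- st$s; fs <- st$fs
  eps <- 1e-9
  best_g <- g; best_s <- s
  tabu_until <- new.env(parent = emptyenv())   # move key -> expiry iteration
  move_key <- function(kind, parent, child) paste(kind, parent, child)
  nonimp <- 0L
  trace <- list()
  for (iter in seq_len(max_iter)) {
    moves <- dag_moves(g, max_parents, blacklist, whitelist)
    if (nrow(moves) == 0L) break
    deltas <- move_deltas(g, moves, fs)
    keys <- move_key(moves$kind, moves$parent, moves$child)
    expiry <- vapply(keys, function(k) tabu_until[[k]] %||% 0L, numeric(1))
    is_tabu <- expiry >= iter
    # aspiration: tabu moves are admissible iff they beat the global best
    admissible <- !is_tabu | (s + deltas > best_s + eps)
    if (!any(admissible)) break
    cand <- which(admissible)
    pick <- cand[which.max(deltas[cand])]
    g <- apply_move(g, moves$kind[pick], moves$parent[pick],
                    moves$child[pick])
    s <- s + deltas[pick]
    inv <- inverse_move(moves$kind[pick], moves$parent[pick],
                        moves$child[pick])
    tabu_until[[move_key(inv[1L], inv[2L], inv[3L])]] <- iter + tenure
    if (s > best_s + eps) {
      best_s <- s; best_g <- g
      nonimp <- 0L
    } else {
      nonimp <- nonimp + 1L
    }
    trace[[length(trace) + 1L]] <- trace_row(
      iter, moves$kind[pick], moves$parent[pick], moves$child[pick],
      deltas[pick], s, best_s)
    if (nonimp >= max_nonimproving) break
  }
  structure(list(dag = best_g, score = best_s,
                 trace = dplyr::bind_rows(trace), algorithm = "tabu",
                 score_type = score),
            class = "hcy_search")
}

#' @export
print.hcy_search <- function(x, ...) {
  cat(sprintf("<hcy_search> %s: %d nodes, %d edges, %s score %.3f (%d iterations)\n",
              x$algorithm, length(x$dag$nodes), nrow(dag_edges(x$dag)),
              x$score_type, x$score, nrow(x$trace)))
  invisible(x)
}

#' @describeIn hill_climb Search trace as a tibble.
#' @param x An `hcy_search` object.
#' @param ... Unused.
#' @method tidy hcy_search
#' @export
tidy.hcy_search <- function(x, ...) x$trace

#' @describeIn hill_climb One-row search summary.
#' @method glance hcy_search
#' @export
glance.hcy_search <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, score_type = x$score_type,
                 score = x$score, n_edges = nrow(dag_edges(x$dag)),
                 iterations = nrow(x$trace))
}
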