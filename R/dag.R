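#' Directed acyclic graph over study variables
#'
#' The structure half of a Bayesian network: nodes are variable names and
#' each directed edge parent -> child asserts a direct dependence. The
#' constructor rejects self-loops, duplicate edges and directed cycles.
#'
#' @param nodes Character vector of node names (unique).
#' @param edges Optional two-column object (data frame or matrix) of edges,
#'   columns parent then child; or `NULL` for the empty graph.
#' @return An object of class `hcy_dag`.
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("node names must be unique")
  p <- length(nodes)
  adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges)) {
    edges <- as.matrix(as.data.frame(edges))
    for (i in seq_len(nrow(edges))) {
      u <- edges[i, 1L]; v <- edges[i, 2L]
      if (!u %in% nodes || !v %in% nodes) {
        abort(sprintf("edge %s -> %s uses an unknown node", u, v))
      }
      if (u == v) abort(sprintf("self-loop at '%s'", u))
      if (adj[u, v]) abort(sprintf("duplicate edge %s -> %s", u, v))
      adj[u, v] <- TRUE
    }
  }
  g <- structure(list(nodes = nodes, adj = adj), class = "hcy_dag")
  if (is.null(topo_sort_adj(adj))) abort("edges form a directed cycle")
  g
}

#' @export
print.hcy_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("<hcy_dag> %d nodes, %d edges\n", length(x$nodes), nrow(e)))
  if (nrow(e) > 0L) {
    cat(sprintf("  %s -> %s\n", e$parent, e$child), sep = "")
  }
  invisible(x)
}

#' @describeIn dag Edge list as a tibble with columns `parent`, `child`.
#' @param x An `hcy_dag`.
#' @export
dag_edges <- function(x) {
  idx <- which(x$adj, arr.ind = TRUE)
  tibble::tibble(parent = x$nodes[idx[, 1L]], child = x$nodes[idx[, 2L]])
}

#' @describeIn dag Parents of `node` (character vector in node order).
#' @param node A node name.
#' @export
dag_parents <- function(x, node) {
  x$nodes[x$adj[, node]]
}

# Kahn topological order on an adjacency matrix; NULL when cyclic.
topo_sort_adj <- function(adj) {
  p <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA            # mark queued
  while (length(avail) > 0L) {
    # smallest index first: deterministic order
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    ch <- which(adj[v, ])
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (!is.na(indeg[w]) && indeg[w] == 0L) {
        avail <- sort(c(avail, w))
        indeg[w] <- NA
      }
    }
  }
  if (length(order) < p) NULL else order
}

#' @describeIn dag Topological order of the node names.
#' @export
topo_sort <- function(x) {
  x$nodes[topo_sort_adj(x$adj)]
}

# TRUE iff a directed path from -> to exists (BFS).
has_path <- function(adj, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(adj))
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier) > 0L) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Legal single-edge moves from a structure
#'
#' Enumerates every edge addition, deletion and reversal whose result is
#' still acyclic and respects the parent-count bound, in deterministic
#' lexicographic order (additions, then deletions, then reversals; within
#' each kind by parent then child name order as given in `nodes`).
#'
#' @param x An `hcy_dag`.
#' @param max_parents Upper bound on any node's parent count (default
#'   `Inf`).
#' @param blacklist Optional data frame of forbidden edges (parent, child):
#'   never added, and reversals may not create them.
#' @param whitelist Optional data frame of protected edges (parent, child):
#'   never deleted or reversed.
#' @return Tibble with columns `kind` (`add`/`delete`/`reverse`), `parent`,
#'   `child` describing each legal move on the current graph.
#' @export
dag_moves <- function(x, max_parents = Inf, blacklist = NULL,
                      whitelist = NULL) {
  nodes <- x$nodes
  adj <- x$adj
  p <- length(nodes)
  npar <- colSums(adj)
  bl <- if (is.null(blacklist)) matrix(FALSE, p, p) else {
    m <- matrix(FALSE, p, p, dimnames = dimnames(adj))
    b <- as.data.frame(blacklist)
    for (i in seq_len(nrow(b))) m[b[[1L]][i], b[[2L]][i]] <- TRUE
    m
  }
  wl <- if (is.null(whitelist)) matrix(FALSE, p, p) else {
    m <- matrix(FALSE, p, p, dimnames = dimnames(adj))
    w <- as.data.frame(whitelist)
    for (i in seq_len(nrow(w))) m[w[[1L]][i], w[[2L]][i]] <- TRUE
    m
  }
  moves <- list()
  for (u in seq_len(p)) for (v in seq_len(p)) {
    if (u == v) next
    if (!adj[u, v] && !adj[v, u]) {
      # addition u -> v: cycle iff path v ~> u already exists
      if (npar[v] < max_parents && !bl[u, v] && !has_path(adj, v, u)) {
        moves[[length(moves) + 1L]] <- c("add", u, v)
      }
    }
  }
  for (u in seq_len(p)) for (v in seq_len(p)) {
    if (adj[u, v] && !wl[u, v]) {
      moves[[length(moves) + 1L]] <- c("delete", u, v)
    }
  }
  for (u in seq_len(p)) for (v in seq_len(p)) {
    if (adj[u, v] && !wl[u, v] && !bl[v, u] && npar[u] < max_parents) {
      # reversal: cycle iff another path u ~> v survives edge removal
      adj2 <- adj; adj2[u, v] <- FALSE
      if (!has_path(adj2, u, v)) {
        moves[[length(moves) + 1L]] <- c("reverse", u, v)
      }
    }
  }
  if (length(moves) == 0L) {
    return(tibble::tibble(kind = character(), parent = character(),
                          child = character()))
  }
  m <- do.call(rbind, moves)
  tibble::tibble(kind = m[, 1L],
                 parent = nodes[as.integer(m[, 2L])],
                 child = nodes[as.integer(m[, 3L])])
}

#' Apply or undo a single-edge move
#'
#' @param x An `hcy_dag`.
#' @param kind `"add"`, `"delete"` or `"reverse"`.
#' @param parent,child Edge endpoints (for a reversal, the edge as it
#'   currently stands, parent -> child).
#' @return The modified `hcy_dag` (still validated acyclic).
#' @export
apply_move <- function(x, kind, parent, child) {
  adj <- x$adj
  switch(kind,
    add = {
      if (adj[parent, child]) abort("edge already present")
      adj[parent, child] <- TRUE
    },
    delete = {
      if (!adj[parent, child]) abort("edge not present")
      adj[parent, child] <- FALSE
    },
    reverse = {
      if (!adj[parent, child]) abort("edge not present")
      adj[parent, child] <- FALSE
      adj[child, parent] <- TRUE
    },
    abort(sprintf("unknown move kind '%s'", kind))
  )
  out <- structure(list(nodes = x$nodes, adj = adj), class = "hcy_dag")
  if (is.null(topo_sort_adj(adj))) abort("move would create a cycle")
  out
}

# Inverse of a move, as a kind/parent/child triple.
inverse_move <- function(kind, parent, child) {
  switch(kind,
    add = c("delete", parent, child),
    delete = c("add", parent, child),
    reverse = c("reverse", child, parent))
}

#' Export a structure in DOT format
#'
#' @param x An `hcy_dag`.
#' @param path Optional file path; when `NULL` the DOT text is returned.
#' @return DOT source as a character scalar (invisibly when written).
#' @export
dag_to_dot <- function(x, path = NULL) {
  e <- dag_edges(x)
  txt <- paste0("digraph bn {\n",
                paste0("  \"", x$nodes, "\";\n", collapse = ""),
                paste0("  \"", e$parent, "\" -> \"", e$child, "\";\n",
                       collapse = ""),
                "}\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
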