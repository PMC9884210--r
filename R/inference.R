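# ---- discrete factor algebra -------------------------------------------
# A factor is list(vars, dims (named), values (array over vars in order)).

new_factor <- function(vars, dims, values) {
  list(vars = vars, dims = dims,
       values = if (length(vars) == 0L) sum(values) else
         array(values, unname(dims[vars])))
}

factor_from_cpt <- function(bn, node) {
  pa <- dag_parents(bn$dag, node)
  vars <- c(node, pa)
  new_factor(vars, setNames(lengths(bn$states[vars]), vars),
             bn$cpts[[node]])
}

# Values of f aligned to the full column-major grid over `vars`.
f_align <- function(f, vars, dims) {
  if (length(f$vars) == 0L) {
    return(rep_len(f$values, prod(dims)))
  }
  grid <- expand.grid(lapply(unname(dims[vars]), seq_len),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vars
  idx <- as.matrix(grid[f$vars])
  if (length(f$vars) == 1L) f$values[idx[, 1L]] else f$values[idx]
}

f_multiply <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  dims <- c(f1$dims, f2$dims)[vars]
  new_factor(vars, dims, f_align(f1, vars, dims) * f_align(f2, vars, dims))
}

f_sum_out <- function(f, var) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  keep <- setdiff(seq_along(f$vars), i)
  if (length(keep) == 0L) {
    return(new_factor(character(0), integer(0), sum(f$values)))
  }
  vals <- apply(f$values, keep, sum)
  new_factor(f$vars[keep], f$dims[f$vars[keep]], vals)
}

f_restrict <- function(f, var, state_idx) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  args <- rep(list(quote(expr = )), length(f$vars))
  args[[i]] <- state_idx
  vals <- do.call(`[`, c(list(f$values), args, list(drop = FALSE)))
  keep <- setdiff(seq_along(f$vars), i)
  if (length(keep) == 0L) {
    return(new_factor(character(0), integer(0), as.numeric(vals)))
  }
  new_factor(f$vars[keep], f$dims[f$vars[keep]], as.numeric(vals))
}

# Min-fill elimination order over the factors' interaction graph,
# deterministic name tie-break.
min_fill_order <- function(factors, eliminate) {
  vars <- sort(unique(unlist(purrr::map(factors, "vars"))))
  adj <- matrix(FALSE, length(vars), length(vars),
                dimnames = list(vars, vars))
  for (f in factors) {
    for (a in f$vars) adj[a, f$vars] <- TRUE
  }
  diag(adj) <- FALSE
  order <- character(0)
  remaining <- sort(intersect(eliminate, vars))
  while (length(remaining) > 0L) {
    fill <- vapply(remaining, function(v) {
      nb <- setdiff(vars[adj[v, ]], order)
      if (length(nb) < 2L) return(0)
      pairs <- utils::combn(nb, 2L)
      sum(!adj[t(pairs)])
    }, numeric(1))
    v <- remaining[which.min(fill)]       # ties: first in name order
    nb <- setdiff(vars[adj[v, ]], order)
    adj[nb, nb] <- TRUE
    diag(adj) <- FALSE
    order <- c(order, v)
    remaining <- setdiff(remaining, v)
  }
  order
}

# Core variable-elimination routine: unnormalised factor over `keep`.
run_ve <- function(bn, keep, evidence = list(), order = NULL) {
  factors <- purrr::map(bn$dag$nodes, function(v) factor_from_cpt(bn, v))
  for (ev in names(evidence)) {
    idx <- match(evidence[[ev]], bn$states[[ev]])
    if (is.na(idx)) {
      abort(sprintf("unknown state '%s' for evidence variable '%s'",
                    evidence[[ev]], ev))
    }
    factors <- purrr::map(factors, f_restrict, var = ev, state_idx = idx)
  }
  elim <- setdiff(bn$dag$nodes, c(keep, names(evidence)))
  if (is.null(order)) order <- min_fill_order(factors, elim)
  order <- unique(c(intersect(order, elim), elim))   # any stragglers last
  for (v in order) {
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    prod_f <- purrr::reduce(factors[touch], f_multiply)
    factors <- c(factors[!touch], list(f_sum_out(prod_f, v)))
  }
  list(result = purrr::reduce(factors, f_multiply), order = order)
}

# ---- user-facing queries ------------------------------------------------

#' Evidence for a probabilistic query
#'
#' @param ... Named state assignments, e.g. `evidence(SBP = "High",
#'   Age = "71-91")`.
#' @return A named list usable as the `evidence` argument of
#'   [posterior()]. Evidence accumulates by concatenation, so a sequential
#'   chain of observations is `c(e1, e2)`.
#' @export
evidence <- function(...) {
  ev <- list(...)
  if (length(ev) > 0L && (is.null(names(ev)) || any(names(ev) == ""))) {
    abort("every evidence assignment must be named")
  }
  if (anyDuplicated(names(ev))) abort("duplicate evidence variable")
  purrr::map(ev, as.character)
}

check_query_vars <- function(bn, vars) {
  bad <- setdiff(vars, bn$dag$nodes)
  if (length(bad) > 0L) {
    abort(paste0("unknown variable(s): ", paste(bad, collapse = ", ")))
  }
}

#' Exact prior marginal of a variable
#'
#' Sums out all other variables by variable elimination (min-fill order).
#'
#' @param bn An `hcy_bn`.
#' @param var Query variable name.
#' @return A tibble (`variable`, `state`, `prob`) with attributes
#'   `evidence` and `elimination_order`; probabilities sum to one.
#' @export
marginal <- function(bn, var) {
  posterior(bn, var, evidence = list())
}

#' Exact posterior under evidence
#'
#' Computes P(var | evidence) by variable elimination with evidence
#' instantiation. Sequential reasoning accumulates evidence by
#' concatenating assignment lists.
#'
#' @param bn An `hcy_bn`.
#' @param var Query variable name.
#' @param evidence Named list of observed states (see [evidence()]).
#' @param order Optional explicit elimination order (character); exact
#'   answers are order-invariant, so this only affects the work done.
#' @return A tibble (`variable`, `state`, `prob`), normalised; errors on
#'   zero-probability (inconsistent) evidence.
#' @export
posterior <- function(bn, var, evidence = list(), order = NULL) {
  check_query_vars(bn, c(var, names(evidence)))
  if (var %in% names(evidence)) {
    prob <- as.numeric(bn$states[[var]] == evidence[[var]])
    if (sum(prob) == 0) abort("evidence state unknown for query variable")
    out <- tibble::tibble(variable = var, state = bn$states[[var]],
                          prob = prob)
    attr(out, "evidence") <- evidence
    attr(out, "elimination_order") <- character(0)
    return(out)
  }
  ve <- run_ve(bn, keep = var, evidence = evidence, order = order)
  vals <- as.numeric(f_align(ve$result, var,
                             setNames(length(bn$states[[var]]), var)))
  z <- sum(vals)
  if (z <= 0) {
    abort(paste0("zero-probability evidence: ",
                 paste(names(evidence), unlist(evidence), sep = "=",
                       collapse = ", ")))
  }
  out <- tibble::tibble(variable = var, state = bn$states[[var]],
                        prob = vals / z)
  attr(out, "evidence") <- evidence
  attr(out, "elimination_order") <- ve$order
  out
}

#' Per-subject predicted state probabilities
#'
#' For every dataset row, the posterior distribution of `target` given all
#' other network variables observed at that row's states — the scoring
#' rule behind the ROC comparison. Computed through the target's Markov
#' blanket (the only families whose probabilities do not cancel), which is
#' exact whenever the evidence has positive probability; rows whose full
#' evidence has probability zero under the network are rescored after
#' dropping a minimal set of conflicting assignments, with a warning.
#'
#' @param bn An `hcy_bn`.
#' @param target Node to predict.
#' @param dataset Coded tibble of factors containing every network node
#'   except possibly `target`.
#' @return A tibble with one probability column per target state, rows
#'   aligned with `dataset`.
#' @export
predict_proba <- function(bn, target, dataset) {
  check_query_vars(bn, target)
  others <- setdiff(bn$dag$nodes, target)
  missing_cols <- setdiff(others, names(dataset))
  if (length(missing_cols) > 0L) {
    abort(paste0("dataset lacks variable(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(dataset)
  r <- length(bn$states[[target]])
  codes <- purrr::map(setNames(others, others), function(v) {
    match(as.character(dataset[[v]]), bn$states[[v]])
  })
  children <- bn$dag$nodes[bn$dag$adj[target, ]]
  fams <- c(target, children)
  res <- matrix(1, n, r)
  for (t in seq_len(r)) {
    for (fam in fams) {
      pa <- dag_parents(bn$dag, fam)
      vars <- c(fam, pa)
      tab <- bn$cpts[[fam]]
      idx <- matrix(0L, n, length(vars))
      for (j in seq_along(vars)) {
        idx[, j] <- if (vars[j] == target) t else codes[[vars[j]]]
      }
      res[, t] <- res[, t] * tab[idx]
    }
  }
  z <- rowSums(res)
  bad <- which(z <= 0 | !is.finite(z))
  if (length(bad) > 0L) {
    warn(sprintf("%d row(s) had zero-probability evidence; conflicting assignments dropped",
                 length(bad)))
    for (i in bad) {
      ev <- purrr::map(setNames(others, others),
                       function(v) as.character(dataset[[v]][i]))
      res[i, ] <- drop_conflicts_posterior(bn, target, ev)
    }
    z <- rowSums(res)
  }
  out <- res / z
  colnames(out) <- bn$states[[target]]
  tibble::as_tibble(out)
}

# Greedily drop evidence assignments until the posterior is well-defined.
drop_conflicts_posterior <- function(bn, target, ev) {
  repeat {
    ans <- tryCatch(posterior(bn, target, ev), error = function(e) NULL)
    if (!is.null(ans)) return(ans$prob)
    if (length(ev) == 0L) {
      abort("no consistent evidence subset found")  # unreachable: empty works
    }
    # drop the single assignment whose removal raises the evidence
    # probability most (first one that makes it positive)
    dropped <- FALSE
    for (v in names(ev)) {
      trial <- ev[setdiff(names(ev), v)]
      ok <- tryCatch({posterior(bn, target, trial); TRUE},
                     error = function(e) FALSE)
      if (ok) {
        ev <- trial
        dropped <- TRUE
        break
      }
    }
    if (!dropped) ev <- ev[-length(ev)]
  }
}
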