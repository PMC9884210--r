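#' Run the full risk-factor analysis pipeline
#'
#' Executes the study's analysis chain on a coded dataset: (1) chi-square
#' screening of every candidate against the outcome; (2) stepwise logistic
#' selection among the screened variables; (3) score-based structure
#' learning over the selected variables plus the outcome, for each
#' requested algorithm; (4) maximum-likelihood CPT estimation; (5) prior
#' marginal of the outcome; (6) in-sample ROC/AUC for each evaluation
#' target under each learned network, plus the structural difference
#' between the algorithms' graphs. All stages are deterministic given the
#' dataset and configuration.
#'
#' @param dataset Coded tibble of factors (e.g. from
#'   [make_hhcy_population()] or [load_dataset()]).
#' @param outcome Binary outcome variable (default `"Hcy"`).
#' @param alpha_screen Univariate screening level (default 0.05).
#' @param alpha_in,alpha_out Stepwise entry/removal thresholds (defaults
#'   0.05 / 0.10).
#' @param algorithms Structure-learning algorithms to run: subset of
#'   `c("tabu", "hc")`.
#' @param score Network score (`"bic"`, `"aic"`, `"loglik"`).
#' @param tenure,max_nonimproving Tabu-search settings (see
#'   [tabu_search()]).
#' @param pseudocount CPT smoothing for [fit_mle()] (default 0).
#' @param eval_targets Nodes to evaluate by ROC (defaults to the outcome
#'   plus `Sex` and `MCR` when present among the learned nodes).
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `hcy_report`: `screen`, `stepwise`, `nodes`,
#'   `searches`, `networks`, `prior`, `rocs` (tibble of AUC results),
#'   `structure_diff` (when two algorithms ran), `config`, `timings`.
#' @export
hcy_pipeline <- function(dataset, outcome = "Hcy",
                         alpha_screen = 0.05, alpha_in = 0.05,
                         alpha_out = 0.10,
                         algorithms = c("tabu", "hc"), score = "bic",
                         tenure = 10L, max_nonimproving = 15L,
                         pseudocount = 0,
                         eval_targets = NULL, quiet = FALSE) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  say("screening %d candidates against %s (alpha = %g)",
      ncol(dataset) - 1L, outcome, alpha_screen)
  screen <- clock("screen",
                  screen_variables(dataset, outcome, alpha = alpha_screen))
  candidates <- screen$variable[screen$selected]
  say("  %d pass screening: %s", length(candidates),
      paste(candidates, collapse = ", "))

  say("stepwise logistic selection (alpha_in = %g, alpha_out = %g)",
      alpha_in, alpha_out)
  stepwise <- clock("stepwise",
                    stepwise_select(dataset, outcome, candidates,
                                    alpha_in = alpha_in,
                                    alpha_out = alpha_out))
  nodes <- c(stepwise$selected, outcome)
  say("  %d selected -> network over %d nodes", length(stepwise$selected),
      length(nodes))

  searches <- list()
  networks <- list()
  for (alg in algorithms) {
    say("structure learning: %s (%s score)", alg, score)
    searches[[alg]] <- clock(paste0("learn_", alg), {
      if (alg == "tabu") {
        tabu_search(dataset, nodes = nodes, score = score, tenure = tenure,
                    max_nonimproving = max_nonimproving)
      } else {
        hill_climb(dataset, nodes = nodes, score = score)
      }
    })
    say("  %s: %d edges, score %.2f", alg,
        nrow(dag_edges(searches[[alg]]$dag)), searches[[alg]]$score)
    networks[[alg]] <- clock(paste0("fit_", alg),
                             fit_mle(dataset, searches[[alg]]$dag,
                                     pseudocount = pseudocount))
  }

  prior <- marginal(networks[[algorithms[1L]]], outcome)

  if (is.null(eval_targets)) {
    eval_targets <- intersect(c(outcome, "Sex", "MCR"), nodes)
  }
  rocs <- clock("evaluate", purrr::map_dfr(algorithms, function(alg) {
    purrr::map_dfr(eval_targets, function(tgt) {
      bn <- networks[[alg]]
      pos_state <- bn$states[[tgt]][length(bn$states[[tgt]])]
      pp <- predict_proba(bn, tgt, dataset)
      r <- roc_auc(pp[[pos_state]], dataset[[tgt]])
      dplyr::mutate(glance(r), algorithm = alg, target = tgt, .before = 1L)
    })
  }))

  structure_diff <- if (length(algorithms) == 2L) {
    compare_structures(searches[[algorithms[1L]]]$dag,
                       searches[[algorithms[2L]]]$dag)
  }

  structure(list(screen = screen, stepwise = stepwise, nodes = nodes,
                 searches = searches, networks = networks, prior = prior,
                 rocs = rocs, structure_diff = structure_diff,
                 config = list(outcome = outcome,
                               alpha_screen = alpha_screen,
                               alpha_in = alpha_in, alpha_out = alpha_out,
                               algorithms = algorithms, score = score,
                               tenure = tenure,
                               max_nonimproving = max_nonimproving,
                               pseudocount = pseudocount,
                               eval_targets = eval_targets),
                 timings = tibble::tibble(stage = names(timings),
                                          seconds = unlist(timings))),
            class = "hcy_report")
}

#' @export
print.hcy_report <- function(x, ...) {
  cat("<hcy_report>\n")
  cat(sprintf("  screened: %d candidates, %d selected by chi-square\n",
              nrow(x$screen), sum(x$screen$selected)))
  cat(sprintf("  stepwise: %s\n", paste(x$stepwise$selected, collapse = ", ")))
  cat(sprintf("  network nodes (%d): %s\n", length(x$nodes),
              paste(x$nodes, collapse = ", ")))
  for (alg in names(x$searches)) {
    cat(sprintf("  %s: %d edges, score %.2f\n", alg,
                nrow(dag_edges(x$searches[[alg]]$dag)),
                x$searches[[alg]]$score))
  }
  pr <- x$prior$prob[length(x$prior$prob)]
  cat(sprintf("  prior P(%s = %s) = %.3f\n", x$config$outcome,
              x$prior$state[length(x$prior$state)], pr))
  print(as.data.frame(x$rocs), digits = 3)
  invisible(x)
}
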