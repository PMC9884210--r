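#' Fit a binary logistic regression on coded variables
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' (relative deviance change below 1e-10, at most 100 iterations), with
#' standard errors from the inverse observed information. Multi-level
#' predictors enter as single ordinal integer scores (0, 1, 2, ... in state
#' order) by default, so each variable carries one coefficient — one odds
#' ratio per band — matching how the published model reports its terms;
#' dummy (treatment) coding is available as an option.
#'
#' @param dataset Coded tibble of factors.
#' @param outcome Binary outcome name; its second factor level is the
#'   modelled event.
#' @param predictors Character vector of predictor names.
#' @param coding `"score"` (default) or `"dummy"`.
#' @return An object of class `hcy_logit`; see [tidy.hcy_logit()] for the
#'   coefficient table (B, SE, Wald p, OR with 95% CI).
#' @export
fit_logistic <- function(dataset, outcome, predictors,
                         coding = c("score", "dummy")) {
  coding <- match.arg(coding)
  y <- dataset[[outcome]]
  if (is.null(y)) abort(sprintf("no variable '%s'", outcome))
  if (nlevels(droplevels(factor(y))) < 2L) {
    abort("outcome is constant: cannot fit a logistic model")
  }
  df <- data.frame(.y = as.integer(factor(y)) - 1L)
  for (v in predictors) {
    col <- dataset[[v]]
    if (is.null(col)) abort(sprintf("no variable '%s'", v))
    df[[v]] <- if (coding == "score") as.integer(col) - 1L else col
  }
  if (nrow(df) <= length(predictors) + 1L) {
    abort("need more subjects than model terms")
  }
  fml <- as.formula(paste(".y ~", if (length(predictors) == 0L) "1" else
    paste(sprintf("`%s`", predictors), collapse = " + ")))
  sep_warned <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = df,
        control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  if (anyNA(b)) {
    abort(paste0("singular design; collinear terms: ",
                 paste(names(b)[is.na(b)], collapse = ", ")))
  }
  converged <- fit$converged && !(sep_warned && any(abs(b) > 10))
  if (!converged) warn("logistic fit did not converge (possible separation)")
  se <- sqrt(diag(vcov(fit)))
  terms <- sub("^`|`$", "", names(b))
  terms[terms == "(Intercept)"] <- "Constant"
  tab <- tibble::tibble(
    term = terms, B = unname(b), SE = unname(se),
    wald_p = 2 * stats::pnorm(-abs(unname(b) / unname(se)))
  )
  tab <- dplyr::bind_cols(tab, odds_ratio(tab$B, tab$SE))
  structure(list(table = tab, loglik = as.numeric(logLik(fit)),
                 df = length(b), n = nrow(df), converged = converged,
                 outcome = outcome, predictors = predictors,
                 coding = coding, glm = fit),
            class = "hcy_logit")
}

#' @export
print.hcy_logit <- function(x, ...) {
  cat(sprintf("<hcy_logit> %s ~ %s\n", x$outcome,
              if (length(x$predictors)) paste(x$predictors, collapse = " + ")
              else "1"))
  cat(sprintf("  n = %d, logLik = %.3f, converged = %s\n",
              x$n, x$loglik, x$converged))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @describeIn fit_logistic Coefficient table as a tibble (term, B, SE,
#'   Wald p, OR, CI95).
#' @param x An `hcy_logit` object.
#' @param ... Unused.
#' @method tidy hcy_logit
#' @export
tidy.hcy_logit <- function(x, ...) x$table

#' @describeIn fit_logistic One-row model summary.
#' @method glance hcy_logit
#' @export
glance.hcy_logit <- function(x, ...) {
  tibble::tibble(n = x$n, df = x$df, loglik = x$loglik,
                 converged = x$converged)
}

#' Odds ratio with 95 percent confidence interval
#'
#' OR = exp(B) and CI = exp(B +/- 1.96 SE), the normal-approximation Wald
#' interval used in the published risk-factor table.
#'
#' @param B Logistic coefficient(s).
#' @param SE Standard error(s), positive.
#' @return A tibble with columns `OR`, `CI_low`, `CI_high`.
#' @export
odds_ratio <- function(B, SE) {
  if (any(SE <= 0)) abort("standard errors must be positive")
  tibble::tibble(OR = exp(B),
                 CI_low = exp(B - 1.96 * SE),
                 CI_high = exp(B + 1.96 * SE))
}

# Likelihood-ratio p-value for nested logistic fits (score coding: 1 df per
# variable; dummy coding: nlevels - 1).
lrt_p <- function(ll_big, ll_small, df) {
  stat <- max(0, 2 * (ll_big - ll_small))
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Stepwise logistic variable selection
#'
#' Forward steps add the candidate with the smallest likelihood-ratio
#' p-value when it is below `alpha_in`; backward steps remove any included
#' term whose likelihood-ratio p-value exceeds `alpha_out`; iteration
#' continues to a fixed point. Ties among equal p-values break
#' lexicographically, so the trace is deterministic.
#'
#' @param dataset Coded tibble of factors.
#' @param outcome Binary outcome name.
#' @param candidates Candidate predictor names (non-empty).
#' @param alpha_in Entry threshold (default 0.05).
#' @param alpha_out Removal threshold (default 0.10); must satisfy
#'   `alpha_in <= alpha_out`.
#' @param max_steps Step budget before the search stops.
#' @param coding Passed to [fit_logistic()].
#' @return A list with `selected` (character vector), `fit` (the final
#'   [fit_logistic()] object) and `trace` (tibble of add/remove steps with
#'   their p-values).
#' @export
stepwise_select <- function(dataset, outcome, candidates,
                            alpha_in = 0.05, alpha_out = 0.10,
                            max_steps = 100L, coding = "score") {
  if (length(candidates) == 0L) abort("no candidates supplied")
  stopifnot(alpha_in > 0, alpha_in <= alpha_out, alpha_out < 1)
  term_df <- function(v) {
    if (coding == "score") 1L else nlevels(droplevels(dataset[[v]])) - 1L
  }
  current <- character(0)
  ll <- function(terms) fit_logistic(dataset, outcome, terms,
                                     coding = coding)$loglik
  ll_cur <- ll(current)
  seen <- character(0)
  trace <- list()
  best <- list(terms = current, loglik = ll_cur)
  for (step in seq_len(max_steps)) {
    key <- paste(sort(current), collapse = "|")
    if (key %in% seen) {
      warn("stepwise selection revisited a model; returning best state")
      current <- best$terms
      break
    }
    seen <- c(seen, key)
    changed <- FALSE
    # forward: smallest LRT p among remaining candidates
    pool <- sort(setdiff(candidates, current))
    if (length(pool) > 0L) {
      ps <- vapply(pool, function(v) {
        lrt_p(ll(c(current, v)), ll_cur, term_df(v))
      }, numeric(1))
      if (min(ps) < alpha_in) {
        add <- pool[which.min(ps)]
        current <- c(current, add)
        ll_cur <- ll(current)
        trace[[length(trace) + 1L]] <- tibble::tibble(
          step = step, action = "add", variable = add, p = min(ps),
          loglik = ll_cur)
        changed <- TRUE
      }
    }
    # backward: any included term with LRT p above alpha_out
    if (length(current) > 0L) {
      ps <- vapply(sort(current), function(v) {
        lrt_p(ll_cur, ll(setdiff(current, v)), term_df(v))
      }, numeric(1))
      if (max(ps) > alpha_out) {
        drop <- names(ps)[which.max(ps)]
        current <- setdiff(current, drop)
        ll_cur <- ll(current)
        trace[[length(trace) + 1L]] <- tibble::tibble(
          step = step, action = "remove", variable = drop, p = max(ps),
          loglik = ll_cur)
        changed <- TRUE
      }
    }
    if (ll_cur > best$loglik || length(best$terms) == 0L) {
      best <- list(terms = current, loglik = ll_cur)
    }
    if (!changed) break
  }
  selected <- current[order(match(current, names(dataset)))]
  list(selected = selected,
       fit = fit_logistic(dataset, outcome, selected, coding = coding),
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(step = integer(), action = character(),
                        variable = character(), p = numeric(),
                        loglik = numeric()))
}
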