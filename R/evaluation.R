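#' ROC curve and AUC with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney probability that a random positive scores
#' above a random negative, ties counting one half (computed by the exact
#' rank formula). The 95 percent confidence interval uses DeLong's
#' asymptotically exact variance estimator.
#'
#' @param scores Numeric vector of predicted probabilities (higher means
#'   more likely positive).
#' @param labels Binary ground truth: logical, 0/1, or a two-level factor
#'   whose second level is the positive class.
#' @param ci Compute the DeLong interval (skipped when `FALSE`).
#' @return An object of class `hcy_roc`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg` and the ROC `curve` tibble (`fpr`, `tpr`,
#'   `threshold`), monotone in both coordinates.
#' @export
roc_auc <- function(scores, labels, ci = TRUE) {
  if (is.factor(labels)) {
    pos <- labels == levels(labels)[2L]
  } else {
    pos <- as.logical(labels)
  }
  stopifnot(length(scores) == length(pos), !anyNA(scores), !anyNA(pos))
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) abort("both classes must be present")
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  band <- if (ci) {
    r <- pROC::roc(response = pos, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1L, 3L)]
  } else c(NA_real_, NA_real_)
  ord <- order(scores, decreasing = TRUE)
  thr <- scores[ord]
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  last <- !duplicated(thr, fromLast = TRUE)     # group tied thresholds
  curve <- tibble::tibble(
    threshold = c(Inf, thr[last]),
    tpr = c(0, tp[last] / n_pos),
    fpr = c(0, fp[last] / n_neg))
  structure(list(auc = auc, ci_low = band[1L], ci_high = band[2L],
                 n_pos = n_pos, n_neg = n_neg, curve = curve),
            class = "hcy_roc")
}

#' @export
print.hcy_roc <- function(x, ...) {
  cat(sprintf("<hcy_roc> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' @describeIn roc_auc ROC curve points as a tibble.
#' @param x An `hcy_roc` object.
#' @param ... Unused.
#' @method tidy hcy_roc
#' @export
tidy.hcy_roc <- function(x, ...) x$curve

#' @describeIn roc_auc One-row AUC summary.
#' @method glance hcy_roc
#' @export
glance.hcy_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Structural difference between two DAGs
#'
#' Edge-set comparison over a common node set: `added` edges appear only
#' in the learned graph, `missing` only in the reference, `reversed` are
#' present in both but with opposite orientation. The structural Hamming
#' distance is their total. Skeleton precision/recall/F1 ignore direction.
#'
#' @param learned,truth Two [dag()]s over the same nodes.
#' @return An object of class `hcy_structdiff` with the edge lists, `shd`
#'   and skeleton metrics; see `glance()` for the one-row summary.
#' @export
compare_structures <- function(learned, truth) {
  if (!setequal(learned$nodes, truth$nodes)) {
    abort("graphs must share the same node set")
  }
  le <- dag_edges(learned)
  te <- dag_edges(truth)
  key <- function(e) paste(e$parent, e$child, sep = "\r")
  rkey <- function(e) paste(e$child, e$parent, sep = "\r")
  reversed <- le[key(le) %in% rkey(te), , drop = FALSE]
  added <- le[!key(le) %in% c(key(te), rkey(te)), , drop = FALSE]
  missing <- te[!key(te) %in% c(key(le), rkey(le)), , drop = FALSE]
  skey <- function(e) {
    vapply(seq_len(nrow(e)), function(i) {
      paste(sort(c(e$parent[i], e$child[i])), collapse = "\r")
    }, character(1))
  }
  ls <- unique(skey(le))
  ts <- unique(skey(te))
  tp <- length(intersect(ls, ts))
  precision <- if (length(ls) == 0L) NA_real_ else tp / length(ls)
  recall <- if (length(ts) == 0L) NA_real_ else tp / length(ts)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  structure(list(n_edges_learned = nrow(le), n_edges_truth = nrow(te),
                 added = added, missing = missing, reversed = reversed,
                 shd = nrow(added) + nrow(missing) + nrow(reversed),
                 skeleton_precision = precision, skeleton_recall = recall,
                 skeleton_f1 = f1),
            class = "hcy_structdiff")
}

#' @export
print.hcy_structdiff <- function(x, ...) {
  cat(sprintf("<hcy_structdiff> SHD %d (added %d, missing %d, reversed %d); skeleton F1 %.3f\n",
              x$shd, nrow(x$added), nrow(x$missing), nrow(x$reversed),
              x$skeleton_f1))
  invisible(x)
}

#' @describeIn compare_structures One-row summary tibble.
#' @param x An `hcy_structdiff` object.
#' @param ... Unused.
#' @method glance hcy_structdiff
#' @export
glance.hcy_structdiff <- function(x, ...) {
  tibble::tibble(n_edges_learned = x$n_edges_learned,
                 n_edges_truth = x$n_edges_truth,
                 shd = x$shd,
                 skeleton_precision = x$skeleton_precision,
                 skeleton_recall = x$skeleton_recall,
                 skeleton_f1 = x$skeleton_f1)
}
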