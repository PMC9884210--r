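#' @describeIn roc_auc ROC curve plot with the AUC in the caption.
#' @param object The object to plot.
#' @method autoplot hcy_roc
#' @export
autoplot.hcy_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  caption = sprintf("AUC %.3f (95%% CI %.3f-%.3f)",
                                    object$auc, object$ci_low,
                                    object$ci_high)) +
    ggplot2::theme_minimal()
}

#' @describeIn dag Circular-layout graph plot of the structure.
#' @param object The object to plot.
#' @param ... Unused.
#' @method autoplot hcy_dag
#' @export
autoplot.hcy_dag <- function(object, ...) {
  nodes <- object$nodes
  p <- length(nodes)
  theta <- seq(0, 2 * pi, length.out = p + 1L)[seq_len(p)]
  pos <- tibble::tibble(node = nodes, x = cos(theta), y = sin(theta))
  e <- dag_edges(object)
  seg <- dplyr::mutate(
    e,
    x = pos$x[match(.data$parent, pos$node)],
    y = pos$y[match(.data$parent, pos$node)],
    xend = pos$x[match(.data$child, pos$node)],
    yend = pos$y[match(.data$child, pos$node)])
  # stop arrows short of the node labels
  shrink <- 0.12
  seg <- dplyr::mutate(
    seg,
    len = sqrt((.data$xend - .data$x)^2 + (.data$yend - .data$y)^2),
    x = .data$x + shrink * (.data$xend - .data$x) / .data$len,
    y = .data$y + shrink * (.data$yend - .data$y) / .data$len,
    xend = .data$xend - shrink * (.data$xend - .data$x) / .data$len,
    yend = .data$yend - shrink * (.data$yend - .data$y) / .data$len)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2.2, "mm"),
                             type = "closed"),
      colour = "grey40") +
    ggplot2::geom_label(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$node), size = 3) +
    ggplot2::coord_equal(xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25)) +
    ggplot2::theme_void()
}

#' @describeIn hill_climb Best-score trace plot of a structure search.
#' @param object The object to plot.
#' @method autoplot hcy_search
#' @export
autoplot.hcy_search <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$score),
                       colour = "grey60") +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_score),
                       colour = "black", linewidth = 0.7) +
    ggplot2::labs(x = "Iteration", y = "Network score",
                  caption = sprintf("%s search, final score %.2f",
                                    object$algorithm, object$score)) +
    ggplot2::theme_minimal()
}

#' Screening results plot
#'
#' Bar chart of -log10 p per candidate with the significance level marked.
#'
#' @param screen Tibble from [screen_variables()].
#' @param alpha Significance level drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_screen <- function(screen, alpha = 0.05) {
  d <- dplyr::mutate(screen,
                     variable = factor(.data$variable,
                                       levels = rev(.data$variable)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variable,
                                  y = -log10(.data$p),
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey30",
                                          `FALSE` = "grey75"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = expression(-log[10]~p)) +
    ggplot2::theme_minimal()
}
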