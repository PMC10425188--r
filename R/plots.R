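# ggplot2 visualizations.

#' @export
autoplot.stage1_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  h$set <- sub("_loss$", "", h$set)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$model$best_epoch,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "KL divergence", colour = NULL,
                  title = "Stage-1 training",
                  subtitle = "dashed line: selected checkpoint") +
    ggplot2::theme_minimal()
}

#' Plot per-residue coiled-coil probability with decoded helices
#'
#' One panel per protein: the posterior coiled-coil probability along the
#' sequence with shaded spans for the decoded helices, colored by the
#' predicted oligomerization state.
#'
#' @param object A `coil_prediction`.
#' @param ids Optional subset of protein ids (default: first 6).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coil_prediction <- function(object, ids = NULL, ...) {
  res <- object$residues
  if (is.null(ids)) ids <- head(unique(res$id), 6L)
  res <- res[res$id %in% ids, , drop = FALSE]
  seg <- object$segments[object$segments$id %in% ids, , drop = FALSE]
  p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$position,
                                         y = .data$cc_probability))
  if (nrow(seg)) {
    p <- p + ggplot2::geom_rect(
      data = seg,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                   fill = .data$oligo_state),
      ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~id, ncol = 1L) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "residue position", y = "P(coiled coil)",
                  fill = "oligomer state") +
    ggplot2::theme_minimal()
}

#' Plot per-measure results of a bootstrap comparison
#'
#' @param comparison Output of [bootstrap_compare()].
#' @return A ggplot object.
#' @export
plot_bootstrap_comparison <- function(comparison) {
  d <- tidyr::pivot_longer(comparison[, c("measure", "mean_a", "mean_b")],
                           c("mean_a", "mean_b"),
                           names_to = "method", values_to = "score")
  d$method <- ifelse(d$method == "mean_a", "A", "B")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$measure, y = .data$score,
                                  fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "bootstrap mean score", fill = "method") +
    ggplot2::theme_minimal()
}
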