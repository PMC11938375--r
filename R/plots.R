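#' Plot a consistent-response map
#'
#' Cluster-by-state heat map of the temporal-maximum consistent-response, the
#' compact summary of combinatorial cell-type tuning.
#'
#' @param object a `carma_cr_map` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.carma_cr_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$state, y = .data$label,
                                       fill = .data$max_cr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "max CR") +
    ggplot2::labs(x = "behavioral state", y = "molecular cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a grouped-ensemble confusion matrix
#'
#' @param object a `carma_grouped` result.
#' @param ... unused.
#' @return a ggplot of the row-normalized mean confusion matrix.
#' @export
autoplot.carma_grouped <- function(object, ...) {
  cm <- tibble::as_tibble(as.data.frame.table(object$confusion,
                                              responseName = "fraction"))
  names(cm)[1:2] <- c("true_state", "decoded_state")
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$decoded_state,
                                   y = .data$true_state,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "decoded state", y = "true state") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an SFFS accuracy path
#'
#' @param object an `sffs_report`.
#' @param ... unused.
#' @return a ggplot of CV accuracy against genes added.
#' @export
autoplot.sffs_report <- function(object, ...) {
  ggplot2::ggplot(object$steps, ggplot2::aes(x = .data$step,
                                             y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene), vjust = -0.8,
                       size = 3) +
    ggplot2::scale_x_continuous(breaks = object$steps$step) +
    ggplot2::labs(x = "genes added", y = "CV accuracy") +
    ggplot2::theme_minimal()
}

#' Plot per-timestamp FDE curves
#'
#' @param object a `carma_temporal_fde` result.
#' @param ... unused.
#' @return a ggplot of FDE over timestamps per gene-set model, with the
#'   shuffle significance level when available.
#' @export
autoplot.carma_temporal_fde <- function(object, ...) {
  p <- ggplot2::ggplot(object$fde, ggplot2::aes(x = .data$timestamp,
                                                y = .data$fde,
                                                color = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "timestamp", y = "fraction of deviance explained") +
    ggplot2::theme_minimal()
  if (!is.null(object$null95)) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(timestamp = seq_along(object$null95),
                            fde = object$null95, model = "shuffle 95th"),
      linetype = "dashed")
  }
  p
}
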