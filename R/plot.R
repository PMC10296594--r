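# ggplot2 views of predictions and evaluations.

SSE_FILLS <- c(H = "#D55E00", E = "#0072B2", L = "#999999", U = "#F0E442")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Secondary-structure track of a prediction
#'
#' One tile per residue along the sequence, colored by label; when truth
#' is available it is drawn as a second row for comparison.
#'
#' @param object An `sse_prediction` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sse_prediction
#' @export
autoplot.sse_prediction <- function(object, ...) {
  rows <- list(tibble::tibble(seq_num = object$seq_num, what = "predicted",
                              label = object$label))
  if (!is.null(object$sse)) {
    rows <- c(rows, list(tibble::tibble(seq_num = object$seq_num,
                                        what = "observed",
                                        label = object$sse)))
  }
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$seq_num, y = .data$what,
                                   fill = .data$label)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(values = SSE_FILLS, name = "SSE") +
    ggplot2::labs(x = "residue", y = NULL,
                  title = trace_source_id(object) %||% NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap of an evaluation
#'
#' @param object An `sse_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sse_eval
#' @export
autoplot.sse_eval <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$confusion))
  names(df) <- c("observed", "predicted", "count")
  df$observed <- factor(df$observed, rev(SSE_CLASSES))
  df$predicted <- factor(df$predicted, SSE_CLASSES)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#0072B2") +
    ggplot2::labs(title = sprintf("accuracy %.3f (n = %d)",
                                  object$accuracy, object$n)) +
    ggplot2::theme_minimal()
}
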