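#' Plot a melt signature
#'
#' Derivative fluorescence against temperature; melting transitions appear
#' as troughs, the rightmost BS1 trough being the internal temperature
#' marker.
#'
#' @param object A `melt_signature`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot melt_signature
#' @export
autoplot.melt_signature <- function(object, ...) {
  df <- tibble::tibble(temperature = object$temperature,
                       value = object$values)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$temperature, .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "Temperature (°C)", y = "dF/dT",
                  title = paste(object$channel, "fluorescent signature")) +
    ggplot2::theme_minimal()
  if (!is.na(object$tm_detected))
    p <- p + ggplot2::geom_vline(xintercept = object$tm_detected,
                                 linetype = "dashed", colour = "grey40")
  p
}

#' Plot overlaid signatures for a set of runs
#'
#' @param sigs Signature tibble from [compute_signatures()].
#' @param channel `"BS1"` or `"BS2"`.
#' @param colour_by Metadata column mapped to colour (default species).
#' @return A ggplot.
#' @export
plot_signatures <- function(sigs, channel = c("BS1", "BS2"),
                            colour_by = "species") {
  channel <- match.arg(channel)
  col <- if (channel == "BS1") "sig_bs1" else "sig_bs2"
  df <- purrr::map2(sigs[[col]], seq_len(nrow(sigs)), function(s, i) {
    tibble::tibble(run_id = sigs$run_id[i],
                   group = as.character(sigs[[colour_by]][i]),
                   temperature = s$temperature, value = s$values)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(.data$temperature, .data$value,
                                   group = .data$run_id,
                                   colour = .data$group)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Temperature (°C)", y = "dF/dT",
                  colour = colour_by,
                  title = paste(channel, "signatures")) +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param object A `confusion_matrix`.
#' @param ... Unused.
#' @return A ggplot tile heatmap (true species on rows).
#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  df$truth <- factor(df$truth, levels = rev(rownames(object)))
  df$predicted <- factor(df$predicted, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b") +
    ggplot2::labs(x = "Predicted species", y = "True species",
                  fill = "runs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Training-history curves of a fitted network
#'
#' @param object A `fann_model`.
#' @param ... Unused.
#' @return A ggplot of accuracy per epoch for training and validation.
#' @method autoplot fann_model
#' @export
autoplot.fann_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            cols = c("train_accuracy", "validation_accuracy"),
                            names_to = "set", values_to = "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$accuracy,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Accuracy (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Top variable-importance bars
#'
#' @param importance Tibble from [variable_importance()].
#' @param top_n Number of features shown.
#' @return A ggplot bar chart of scaled importance.
#' @export
plot_importance <- function(importance, top_n = 20) {
  df <- utils::head(importance, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$scaled_importance, .data$feature)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Scaled importance", y = NULL) +
    ggplot2::theme_minimal()
}
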