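#' Plot PCA QC scores
#'
#' PC1 vs PC2, colored by batch, shaped by histotype group — the view used
#' to judge batch structure before and after [remove_batch_effect()].
#'
#' @param object A [pca_qc()] result.
#' @param color Column mapped to color (default `"batch"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirlink_pca <- function(object, color = "batch", ...) {
  ve <- attr(object, "var_explained")
  lab <- function(k) {
    if (!is.null(ve) && length(ve) >= k) {
      sprintf("PC%d (%.1f%%)", k, 100 * ve[k])
    } else {
      paste0("PC", k)
    }
  }
  ggplot2::ggplot(object, ggplot2::aes(.data$PC1, .data$PC2,
                                       color = .data[[color]],
                                       shape = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of a differential expression table
#'
#' `log2` median-based fold change against `-log10` FDR, significant
#' features highlighted.
#'
#' @param object A [differential_table()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirlink_de <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$neglog_fdr <- -log10(pmax(df$fdr, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(log2(.data$mbfc), .data$neglog_fdr,
                                   color = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 median-based fold change",
                  y = "-log10 FDR", color = "significant") +
    ggplot2::theme_minimal()
}

#' Bar chart of candidate-funnel stage counts
#'
#' @param object A [build_funnel()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirlink_funnel <- function(object, ...) {
  df <- object$funnel
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(title = paste("Candidate funnel:", object$group),
                  x = NULL, y = "pairs") +
    ggplot2::theme_minimal()
}

#' Distribution of screened correlation coefficients
#'
#' Histogram of Spearman `r` across all screened pairs with the
#' inverse-correlation threshold marked.
#'
#' @param object An [all_pairs_screen()] (or filtered) result.
#' @param threshold Threshold line to draw (default -0.6).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mirlink_screen <- function(object, threshold = -0.6, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$r)) +
    ggplot2::geom_histogram(bins = 80, fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold, color = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "Spearman r", y = "pairs") +
    ggplot2::theme_minimal()
}
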