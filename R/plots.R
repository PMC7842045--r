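## ggplot2 views of fitted stores and concordance reports.

#' @describeIn evaluate_concordance Histogram of per-sample intra-sample
#'   R^2 with the median marked.
#' @param object A `methcorr_concordance` tibble.
#' @param ... Unused.
#' @export
autoplot.methcorr_concordance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = attr(object, "median_r2"),
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(
      x = expression("intra-sample" ~ R^2 ~ "(inferred vs observed)"),
      y = "samples",
      title = "Concordance of inferred with observed expression",
      subtitle = paste0("median R² = ",
                        signif(attr(object, "median_r2"), 3))
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn model_store Discovery vs validation R^2 for every stored
#'   gene model, coloured by chosen polynomial degree.
#' @param object A `methcorr_model_store`.
#' @param ... Unused.
#' @export
autoplot.methcorr_model_store <- function(object, ...) {
  df <- object$models
  df$degree <- factor(df$degree)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r2_discovery,
                                   y = .data$r2_validation,
                                   colour = .data$degree)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = expression("discovery" ~ R^2),
                  y = expression("validation" ~ R^2),
                  colour = "degree",
                  title = "Per-gene model performance") +
    ggplot2::theme_minimal()
}

#' Plot one gene's MCS-to-expression fit
#'
#' Scatter of expression against MethCORR score with the fitted polynomial
#' overlaid.
#'
#' @param model A `methcorr_gene_model`.
#' @param mcs,expr Aligned score and expression vectors (e.g. the discovery
#'   samples the model was fit on).
#' @return A ggplot object.
#' @export
plot_gene_fit <- function(model, mcs, expr) {
  stopifnot(inherits(model, "methcorr_gene_model"))
  df <- tibble::tibble(mcs = mcs, expr = expr)
  grid <- tibble::tibble(mcs = seq(0, 1, length.out = 200))
  grid$fit <- predict(model, grid$mcs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mcs, y = .data$expr)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::labs(x = "MethCORR score", y = "expression",
                  title = paste0(model$gene, " (degree ", model$degree, ")")) +
    ggplot2::theme_minimal()
}
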