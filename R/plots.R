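# ggplot2 displays for the main result types.

#' Plot mined structural alerts
#'
#' Bar chart of occurrence counts per alert, filled by precision; alerts
#' with infinite likelihood ratio are marked.
#'
#' @param rules An `alert_rules` tibble from [mine_alerts()].
#' @return A ggplot object.
#' @export
plot_alert_rules <- function(rules) {
  df <- tibble::as_tibble(rules)
  df$rule <- factor(df$id, levels = rev(df$id))
  df$lr_class <- ifelse(is.infinite(df$lr), "infinite LR", "finite LR")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tp, y = .data$rule,
                                   fill = .data$precision_pct)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lr_class),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "active compounds matched", y = "alert rule",
                  fill = "precision (%)") +
    ggplot2::theme_minimal()
}

#' Plot a drug-property contrast
#'
#' Side-by-side per-term possession fractions for the hepatoprotective and
#' non-hepatoprotective groups, faceted by property family.
#'
#' @param hepato,non_hepato `property_matrix` objects.
#' @return A ggplot object.
#' @export
plot_property_contrast <- function(hepato, non_hepato) {
  frac <- function(pm, grp) {
    tibble::tibble(term = property_vocabulary(),
                   fraction = colMeans(prop_values(pm)), group = grp)
  }
  df <- dplyr::bind_rows(frac(hepato, "hepatoprotective"),
                         frac(non_hepato, "non-hepatoprotective")) |>
    dplyr::left_join(property_families(), by = "term")
  df$term <- factor(df$term, levels = property_vocabulary())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$fraction,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$family), scales = "free_x",
                        space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "fraction of herbs", fill = NULL)
}

#' Plot the material-basis degree distribution
#'
#' Lollipop chart of active-ingredient counts per herb with the candidate
#' threshold marked.
#'
#' @param degrees Tibble from [ingredient_degree()].
#' @param min_count Threshold to mark (default 15).
#' @param top Show at most this many herbs (default 40).
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(degrees, min_count = 15, top = 40) {
  df <- utils::head(degrees[order(-degrees$n_active_ingredients), ], top)
  df$herb <- factor(df$herb, levels = rev(df$herb))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_active_ingredients,
                                   y = .data$herb)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$n_active_ingredients,
                                       yend = .data$herb), linewidth = 0.3) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = min_count, linetype = "dashed") +
    ggplot2::labs(x = "distinct hepatoprotective ingredients", y = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve of a cross-validation result
#'
#' @param object An `hs_cv` object from [crossvalidate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_cv <- function(object, ...) {
  sc <- object$scores[order(-object$scores$score), ]
  df <- tibble::tibble(
    fpr = cumsum(!sc$active) / sum(!sc$active),
    tpr = cumsum(sc$active) / sum(sc$active)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = sprintf("%d-fold CV, %s (AUC = %.3f)", object$k,
                      object$spec$name, object$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
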