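#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_line
#'   geom_abline geom_col scale_size_area labs theme_minimal coord_equal
NULL

#' @export
ggplot2::autoplot

#' Bubble plot of an association atlas
#'
#' Antigens against features, bubble size proportional to `-log10 p`, solid
#' bubbles for associations below `alpha`.
#'
#' @param object A `sero_atlas`.
#' @param alpha Significance highlight level (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sero_atlas
#' @export
autoplot.sero_atlas <- function(object, alpha = 0.05, ...) {
  d <- object[object$tested, , drop = FALSE]
  d$neglog10p <- -log10(pmax(d$p, 1e-300))
  d$significant <- d$p < alpha
  ggplot(d, aes(x = .data$feature, y = .data$antigen,
                size = .data$neglog10p, alpha = .data$significant)) +
    geom_point() +
    scale_size_area(max_size = 6) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.25, `TRUE` = 1),
                                guide = "none") +
    labs(x = NULL, y = NULL, size = "-log10 p") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' ROC curve plot
#'
#' @param object A `sero_roc`.
#' @param ... Unused.
#' @return A ggplot of sensitivity against 1 - specificity with the chance
#'   diagonal.
#' @method autoplot sero_roc
#' @export
autoplot.sero_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' Prevalence-band heatmap
#'
#' Antigens against cohort groups, tiles shaded by prevalence band.
#'
#' @param object A `sero_prevalence` table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sero_prevalence
#' @export
autoplot.sero_prevalence <- function(object, ...) {
  ggplot(object, aes(x = .data$group, y = .data$antigen, fill = .data$band)) +
    geom_tile() +
    ggplot2::scale_fill_manual(values = c("<5%" = "#ece7f2",
                                          "5-10%" = "#a6bddb",
                                          ">10%" = "#2b8cbe")) +
    labs(x = NULL, y = NULL, fill = "Prevalence") +
    theme_minimal()
}

#' Seroconversion category barplot
#'
#' Per-patient stacked counts of the four conversion categories (stable
#' negatives omitted by default, mirroring repertoire-focused displays).
#'
#' @param summary A `sero_conversion_summary`.
#' @param include_stable_negative Keep the stable-negative slots.
#' @return A ggplot.
#' @export
plot_conversions <- function(summary, include_stable_negative = FALSE) {
  stopifnot(inherits(summary, "sero_conversion_summary"))
  d <- tidyr::pivot_longer(summary$per_patient, -"patient",
                           names_to = "category", values_to = "n")
  if (!include_stable_negative) {
    d <- d[d$category != "stable-negative", , drop = FALSE]
  }
  ggplot(d, aes(x = .data$patient, y = .data$n, fill = .data$category)) +
    geom_col() +
    labs(x = NULL, y = "Antigen slots", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
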