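#' Plot an individualized FIT cut-off table
#'
#' Cut-off concentration against age, one line per sex, with the assay
#' limit of detection as a dashed reference — the lookup-figure view of
#' [cutoff_table()].
#'
#' @param object A `fit_cutoff_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fit_cutoff_table <- function(object, ...) {
  lod <- attr(object, "lod")
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data$age_years, y = .data$fit_cutoff_ug_g,
      colour = .data$sex, linetype = .data$sex
    )
  ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = lod, linetype = "dashed", colour = "grey40") +
    ggplot2::annotate(
      "text",
      x = min(object$age_years), y = lod, vjust = -0.5, hjust = 0,
      label = "assay LOD", size = 3, colour = "grey40"
    ) +
    ggplot2::labs(
      x = "Age (years)",
      y = expression("FIT cut-off (" * mu * "g Hb/g faeces)"),
      colour = "Sex", linetype = "Sex",
      title = sprintf(
        "Individualized FIT cut-offs at risk threshold %.4f",
        attr(object, "risk_threshold")
      )
    ) +
    ggplot2::theme_minimal()
}

#' ROC curves of the risk model and FIT alone
#'
#' @param data Cohort data frame.
#' @param model An `an_risk_model`.
#' @return A ggplot object with both empirical ROC curves.
#' @export
plot_roc_curves <- function(data, model) {
  validate_cohort(data)
  labels <- data$advanced_neoplasia == 1L
  coords <- dplyr::bind_rows(
    roc_points(predict_risk(model, data), labels, "risk model"),
    roc_points(data$fit_ug_g, labels, "FIT")
  )
  ggplot2::ggplot(
    coords,
    ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$strategy)
  ) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity", colour = NULL,
      title = "ROC: risk model vs FIT concentration"
    ) +
    ggplot2::theme_minimal()
}

#' Sensitivity of FIT and the risk model at matched specificity
#'
#' Dot plot of the two strategies' sensitivities across the reference
#' FIT cut-offs, as produced by [matched_sensitivity_table()].
#'
#' @param table Output of [matched_sensitivity_table()].
#' @return A ggplot object.
#' @export
plot_matched_sensitivity <- function(table) {
  long <- tidyr::pivot_longer(
    table,
    cols = c("fit_sensitivity", "risk_sensitivity"),
    names_to = "strategy", values_to = "sensitivity"
  )
  long$strategy <- ifelse(
    long$strategy == "fit_sensitivity", "FIT", "risk model"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = factor(.data$reference_cutoff), y = .data$sensitivity,
      colour = .data$strategy, group = .data$strategy
    )
  ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression("Reference FIT cut-off (" * mu * "g Hb/g)"),
      y = "Sensitivity", colour = NULL,
      title = "Sensitivity at matched specificity"
    ) +
    ggplot2::theme_minimal()
}
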