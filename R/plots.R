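# ggplot2 visualisations for the main result types.

#' @describeIn saliency_map One-dimensional heatmap of the saliency values
#'   over the HT and FT channels; the padded tail (if known) is dimmed.
#' @param object An `fmi_saliency` object.
#' @param ... Unused.
#' @export
autoplot.fmi_saliency <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$channel,
                                       fill = .data$saliency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "keystroke sample", y = NULL, fill = "saliency",
                  title = sprintf("Input attribution (%s, prediction %.2f)",
                                  object$index_name, object$prediction)) +
    ggplot2::theme_minimal()
  if (!anyNA(d$padded) && any(d$padded)) {
    p <- p + ggplot2::geom_vline(xintercept = object$n_real + 0.5,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' @describeIn roc_auc ROC curve (sensitivity vs 1 - specificity).
#' @param object An `fmi_roc` object.
#' @export
autoplot.fmi_roc <- function(object, ...) {
  d <- dplyr::arrange(object$operating_points, .data$sensitivity)
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step(colour = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Indices versus clinical item scores
#'
#' Scatter of each typing-based index against its clinical item score, with
#' a linear fit, coloured by group (HC green, PD red).
#'
#' @param indices An index tibble from [compute_indices()].
#' @param manifest A manifest tibble with group and `updrs_*` columns.
#' @return A ggplot object (facetted by index).
#' @export
plot_indices_vs_items <- function(indices, manifest) {
  dat <- dplyr::inner_join(indices, manifest, by = "subject_id")
  long <- dplyr::bind_rows(lapply(
    list(c("dRSi", "updrs_22"), c("dAFSi", "updrs_23"), c("dBSi", "updrs_31")),
    function(pair) {
      tibble::tibble(index = pair[1], group = dat$group,
                     score = dat[[pair[2]]], value = dat[[pair[1]]])
    }
  ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, colour = "black", linewidth = 0.5) +
    ggplot2::scale_colour_manual(values = c(HC = "#1b7837", PD = "#b2182b")) +
    ggplot2::facet_wrap(~index, scales = "free") +
    ggplot2::labs(x = "UPDRS Part III item score", y = "typing-based index") +
    ggplot2::theme_minimal()
}

#' Hourly severity series against the ON/OFF trapezoid
#'
#' @param series Output of [hourly_median_index()].
#' @param gt Output of [build_onoff_ground_truth()].
#' @return A ggplot object; the index series is min-max scaled onto \[0, 1\]
#'   for visual comparison with the trapezoid.
#' @export
plot_onoff <- function(series, gt) {
  rng <- range(series$median_index)
  scaled <- (series$median_index - rng[1]) / max(rng[2] - rng[1], 1e-12)
  sdat <- tibble::tibble(hour = series$hour + 0.5, value = scaled)
  ggplot2::ggplot() +
    ggplot2::geom_line(data = gt, ggplot2::aes(x = .data$time_hours, y = .data$value),
                       colour = "#2166ac", linetype = "dashed") +
    ggplot2::geom_step(data = sdat, ggplot2::aes(x = .data$hour, y = .data$value),
                       colour = "grey30") +
    ggplot2::geom_point(data = sdat, ggplot2::aes(x = .data$hour, y = .data$value),
                        colour = "#e08214") +
    ggplot2::labs(x = "hour of day",
                  y = "ON/OFF ground truth / scaled median index",
                  title = "Medication state vs hourly median severity index") +
    ggplot2::theme_minimal()
}
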