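#' Gradient saliency map for one typing input
#'
#' Computes the gradient of the model's scalar severity output with respect
#' to the 2 x 100 HT/FT input, takes absolute values per channel and
#' max-normalizes the map to \[0, 1\] (unless it is identically zero). High
#' values mark the samples of the typing session that drive the severity
#' prediction. Attribution falling on the zero-padded tail is reported but
#' flagged.
#'
#' @param model A fitted [fit_hybrid()] model (differentiable stack).
#' @param input One 2 x 100 input matrix, or a one-row model-input tibble
#'   (whose `n_real` column flags the padding boundary).
#' @param n_real Optional unpadded length, used to flag padded samples when
#'   `input` is a bare matrix.
#' @return An object of class `fmi_saliency`: `values` (2 x 100 matrix,
#'   rownames `ht`/`ft`), `prediction`, `n_real`, `index_name`. `tidy()`
#'   returns a long tibble `channel`, `sample`, `saliency`, `padded`.
#' @export
saliency_map <- function(model, input, n_real = NULL) {
  if (!inherits(model, "fmi_hybrid")) {
    abort_bad_arg("`model` must be a fitted fmi_hybrid (differentiable) model.",
                  "fmikeys_unsupported_model_error")
  }
  if (is.data.frame(input)) {
    if (nrow(input) != 1) {
      abort_bad_arg("Pass exactly one input row to saliency_map().",
                    "fmikeys_validation_error")
    }
    if (is.null(n_real) && "n_real" %in% names(input)) n_real <- input$n_real
    input <- input$input[[1]]
  }
  if (!is.matrix(input) || !all(dim(input) == c(2, 100))) {
    abort_bad_arg("`input` must be a 2 x 100 matrix.", "fmikeys_validation_error")
  }
  X <- array(input, c(2L, 100L, 1L))
  fwd <- nn_forward(model$layers, X)
  grad <- nn_backward(model$layers, fwd$caches, matrix(1, 1L, 1L))$dX
  sal <- abs(array(grad, c(2L, 100L)))
  mx <- max(sal)
  if (mx > 0) sal <- sal / mx
  rownames(sal) <- c("ht", "ft")
  structure(
    list(values = sal, prediction = as.numeric(fwd$out),
         n_real = if (is.null(n_real)) NA_integer_ else as.integer(n_real),
         index_name = model$index_name),
    class = "fmi_saliency"
  )
}

#' @export
tidy.fmi_saliency <- function(x, ...) {
  tibble::tibble(
    channel = rep(c("ht", "ft"), each = 100L),
    sample = rep(seq_len(100L), 2L),
    saliency = c(x$values["ht", ], x$values["ft", ]),
    padded = if (is.na(x$n_real)) NA else rep(seq_len(100L) > x$n_real, 2L)
  )
}

#' @export
print.fmi_saliency <- function(x, ...) {
  peak <- which.max(apply(x$values, 2, max))
  cat(sprintf("<fmi_saliency> %s prediction %.3f; peak attribution at sample %d\n",
              x$index_name, x$prediction, peak))
  invisible(x)
}

#' Trapezoid medication ON/OFF ground truth
#'
#' Builds the piecewise-linear reference signal for medication state over the
#' analysis window: 1 on ON plateaus, 0 on OFF plateaus, linear over the
#' transition minutes before and after each ON phase. Overlapping ON phases
#' are merged (pointwise maximum) with a warning.
#'
#' @param schedule An [onoff_schedule()].
#' @param resolution_min Grid resolution in minutes (default 1).
#' @return A tibble `time_hours`, `value` over the schedule's day window.
#' @export
build_onoff_ground_truth <- function(schedule, resolution_min = 1) {
  stopifnot(inherits(schedule, "onoff_schedule"))
  spans <- cbind(schedule$intake_times,
                 schedule$intake_times + schedule$on_duration / 60)
  if (nrow(spans) > 1 &&
      any(spans[-1, 1] < spans[-nrow(spans), 2] + schedule$transition / 60)) {
    warning("Overlapping ON periods; merged by pointwise maximum.", call. = FALSE)
  }
  t <- seq(schedule$window[1], schedule$window[2], by = resolution_min / 60)
  tibble::tibble(time_hours = t, value = onoff_envelope(schedule, t))
}

#' Hourly median of per-session severity estimates
#'
#' Aggregates session-level predictions to an hour-of-day series: within
#' each hour the median of the (by default absolute) estimates. Hours with
#' no sessions are absent from the output, not zero-filled.
#'
#' @param predictions A tibble with `start_time` (POSIXct) and a numeric
#'   estimate column.
#' @param value_col Name of the estimate column (default `"prediction"`).
#' @param absolute Take absolute values before the median (default `TRUE`,
#'   the convention used for plotting the bradykinesia index).
#' @return A tibble `hour`, `median_index`, `n_sessions`.
#' @export
hourly_median_index <- function(predictions, value_col = "prediction",
                                absolute = TRUE) {
  if (nrow(predictions) == 0) {
    abort_bad_arg("No predictions to aggregate.", "fmikeys_validation_error")
  }
  if (!value_col %in% names(predictions)) {
    abort_bad_arg(sprintf("Column `%s` not found in predictions.", value_col),
                  "fmikeys_validation_error")
  }
  v <- predictions[[value_col]]
  if (absolute) v <- abs(v)
  hr <- as.integer(format(predictions$start_time, "%H"))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(hour = hr, v = v), .data$hour),
    median_index = stats::median(.data$v),
    n_sessions = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$hour)
}

#' Correlation of the hourly severity series with the ON/OFF ground truth
#'
#' The trapezoid ground truth is averaged within each hour to match the
#' hourly resolution of the index series, then the Pearson correlation over
#' the overlapping hours is computed. Because severity rises when medication
#' wears OFF (ground truth 0) the expected association is negative.
#'
#' @param series Output of [hourly_median_index()].
#' @param gt Output of [build_onoff_ground_truth()].
#' @return A one-row tibble `r`, `p_value`, `n_hours`.
#' @export
onoff_correlation <- function(series, gt) {
  gt_hour <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(gt, hour = floor(.data$time_hours)), .data$hour),
    gt_value = mean(.data$value), .groups = "drop"
  )
  joined <- dplyr::inner_join(series, gt_hour, by = "hour")
  if (nrow(joined) < 3) {
    abort_bad_arg("Need at least 3 overlapping hours for the ON/OFF correlation.",
                  "fmikeys_validation_error")
  }
  pc <- pearson_correlation(joined$median_index, joined$gt_value)
  tibble::tibble(r = pc$r, p_value = pc$p_value, n_hours = nrow(joined))
}
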