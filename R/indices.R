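#' Subject-level aggregation of per-session severity estimates
#'
#' In-the-clinic sessions follow a controlled protocol with similar
#' per-session distributions, so the subject's severity is the arithmetic
#' mean of the session estimates. In-the-wild contributions vary much more
#' across sessions, so the three quartiles (25th/50th/75th, linear
#' interpolation between order statistics) summarise the subject, with the
#' median as the default scalar index.
#'
#' @param session_estimates Non-empty numeric vector of per-session severity
#'   estimates for one subject.
#' @return `aggregate_subject_clinic()`: a single number (the mean).
#'   `aggregate_subject_wild()`: a one-row tibble `q25`, `q50`, `q75`,
#'   `index`.
#' @export
#' @examples
#' aggregate_subject_clinic(c(1, 2, 3))       # 2
#' aggregate_subject_wild(c(1, 2, 3, 4))$q25  # 1.75
aggregate_subject_clinic <- function(session_estimates) {
  if (length(session_estimates) == 0) {
    abort_bad_arg("Cannot aggregate an empty list of session estimates.",
                  "fmikeys_validation_error")
  }
  mean(session_estimates)
}

#' @rdname aggregate_subject_clinic
#' @param index Which quartile to report as the scalar in-the-wild index:
#'   `"q50"` (default), `"q25"` or `"q75"`.
#' @export
aggregate_subject_wild <- function(session_estimates, index = "q50") {
  if (length(session_estimates) == 0) {
    abort_bad_arg("Cannot aggregate an empty list of session estimates.",
                  "fmikeys_validation_error")
  }
  index <- match.arg(index, c("q50", "q25", "q75"))
  q <- quartiles_linear(session_estimates)
  out <- tibble::tibble(q25 = q[1], q50 = q[2], q75 = q[3])
  out$index <- out[[index]]
  out
}

#' Compute per-subject severity indices from the three hybrid models
#'
#' Combines per-session predictions of the three severity regressors into
#' the typing-based indices dRSi (item 22, rigidity), dAFSi (item 23,
#' alternate finger tapping) and dBSi (item 31, body brady/hypokinesia).
#' Segment predictions are first averaged within each session, then sessions
#' are aggregated per subject in the chosen mode.
#'
#' @param predictions Named list with elements `"22"`, `"23"`, `"31"` — each
#'   a per-input prediction tibble with columns `subject_id`, `session_id`,
#'   `prediction` (e.g. `tidy()` of an [finetune_loso()] fit, or
#'   [predict.fmi_hybrid()] output).
#' @param mode `"wild"` (quartile aggregation, default) or `"clinic"` (mean).
#' @param wild_index Scalar quartile for wild mode (default `"q50"`).
#' @return A tibble with one row per subject: `subject_id`,
#'   `n_valid_sessions`, the indices `dRSi`, `dAFSi`, `dBSi` and, per index,
#'   `q25_*`, `q50_*`, `q75_*`. Per-session estimates are attached as the
#'   `"session_estimates"` attribute (see [session_estimates()]).
#' @export
compute_indices <- function(predictions, mode = c("wild", "clinic"),
                            wild_index = "q50") {
  mode <- match.arg(mode)
  items <- c("22", "23", "31")
  if (!all(items %in% names(predictions))) {
    abort_bad_arg("`predictions` must be a named list with elements \"22\", \"23\", \"31\".",
                  "fmikeys_config_error")
  }
  per_item <- lapply(items, function(it) {
    p <- predictions[[it]]
    if (!all(c("subject_id", "session_id", "prediction") %in% names(p))) {
      abort_bad_arg(sprintf("Prediction table for item %s lacks required columns.", it),
                    "fmikeys_validation_error")
    }
    sess <- dplyr::summarise(
      dplyr::group_by(p, .data$subject_id, .data$session_id),
      estimate = mean(.data$prediction),
      start_time = if ("start_time" %in% names(p)) .data$start_time[1] else
        as.POSIXct(NA),
      .groups = "drop"
    )
    sess$item <- it
    sess
  })
  sessions_long <- dplyr::bind_rows(per_item)

  idx_rows <- lapply(items, function(it) {
    nm <- index_name_for_item(it)
    sess <- sessions_long[sessions_long$item == it, , drop = FALSE]
    by_subj <- dplyr::summarise(
      dplyr::group_by(sess, .data$subject_id),
      n_valid_sessions = dplyr::n(),
      q25 = quartiles_linear(.data$estimate)[1],
      q50 = quartiles_linear(.data$estimate)[2],
      q75 = quartiles_linear(.data$estimate)[3],
      m = mean(.data$estimate),
      .groups = "drop"
    )
    by_subj$value <- if (mode == "clinic") by_subj$m else by_subj[[wild_index]]
    names(by_subj)[names(by_subj) == "q25"] <- paste0("q25_", nm)
    names(by_subj)[names(by_subj) == "q50"] <- paste0("q50_", nm)
    names(by_subj)[names(by_subj) == "q75"] <- paste0("q75_", nm)
    names(by_subj)[names(by_subj) == "value"] <- nm
    by_subj$m <- NULL
    by_subj
  })
  out <- idx_rows[[1]]
  for (i in 2:3) {
    out <- dplyr::left_join(out, dplyr::select(idx_rows[[i]], -"n_valid_sessions"),
                            by = "subject_id")
  }
  ord <- c("subject_id", "n_valid_sessions", "dRSi", "dAFSi", "dBSi",
           setdiff(names(out), c("subject_id", "n_valid_sessions",
                                 "dRSi", "dAFSi", "dBSi")))
  out <- out[, ord]
  attr(out, "session_estimates") <- sessions_long
  attr(out, "mode") <- mode
  out
}

#' Per-session severity estimates behind an index table
#'
#' @param indices A tibble returned by [compute_indices()].
#' @return A long tibble `subject_id`, `session_id`, `estimate`,
#'   `start_time`, `item`.
#' @export
session_estimates <- function(indices) {
  se <- attr(indices, "session_estimates")
  if (is.null(se)) {
    abort_bad_arg("`indices` carries no session estimates; was it built by compute_indices()?",
                  "fmikeys_validation_error")
  }
  se
}

#' Summarise pipeline metrics across random states
#'
#' The networks' performance is assessed across several random states
#' (seeds); this summarises each metric by its mean and standard deviation
#' over the runs.
#'
#' @param runs A data frame with one row per run, a `seed` column and one
#'   numeric column per metric; or a list of named numeric vectors.
#' @return A tibble `metric`, `mean`, `sd`, `n_seeds`.
#' @export
#' @examples
#' multi_seed_summary(data.frame(seed = 1:3, r = c(0.5, 0.6, 0.7)))
multi_seed_summary <- function(runs) {
  if (is.list(runs) && !is.data.frame(runs)) {
    runs <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
      tibble::as_tibble(c(list(seed = i), as.list(runs[[i]])))
    }))
  }
  if (nrow(runs) < 2) {
    abort_bad_arg("Need at least 2 runs to summarise across seeds.",
                  "fmikeys_validation_error")
  }
  metrics <- setdiff(names(runs), "seed")
  dplyr::bind_rows(lapply(metrics, function(m) {
    tibble::tibble(metric = m, mean = mean(runs[[m]]), sd = stats::sd(runs[[m]]),
                   n_seeds = nrow(runs))
  }))
}
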