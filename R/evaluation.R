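#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper around the standard t-transform test, returning a tidy row.
#' Used to score severity indices against clinical item scores.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), both with non-zero
#'   variance.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
#' @examples
#' pearson_correlation(c(1, 2, 3), c(2, 4, 6))$r  # 1
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort_bad_arg("`x` and `y` must have equal length >= 3.",
                  "fmikeys_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_bad_arg("Correlation undefined: zero variance in `x` or `y`.",
                  "fmikeys_validation_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    abort_bad_arg("`labels` must be 0/1.", "fmikeys_validation_error")
  }
  if (length(unique(labels)) < 2) {
    abort_bad_arg("Both classes must be present to compute a ROC curve.",
                  "fmikeys_validation_error")
  }
  labels
}

# AUC as the pairwise concordance probability (ties counted 1/2), via the
# rank / Mann-Whitney identity.
auc_stat <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Operating points sweeping "predict positive if score >= t" over unique
# scores (plus an all-positive and an all-negative endpoint).
roc_points <- function(scores, labels) {
  th <- c(-Inf, sort(unique(scores)), Inf)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  tibble::tibble(
    threshold = th,
    sensitivity = vapply(th, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(th, function(t) mean(neg < t), numeric(1))
  )
}

#' ROC curve and area under it
#'
#' The AUC is the probability that a random positive outscores a random
#' negative, with ties counted one half (the Mann-Whitney normalization);
#' the curve is swept over all unique score thresholds. Optionally a
#' percentile bootstrap confidence interval is attached.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels 0/1 class labels (1 = positive/PD); both classes required.
#' @param ci Compute a bootstrap CI? Default `FALSE`.
#' @param n_bootstrap Bootstrap resamples for the CI (default 1000).
#' @param seed Seed for the bootstrap (default 1).
#' @return An object of class `fmi_roc`: `auc`, `ci_low`/`ci_high` (NA
#'   unless `ci`), `operating_points` tibble, counts and bootstrap metadata.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc  # 1
roc_auc <- function(scores, labels, ci = FALSE, n_bootstrap = 1000, seed = 1L) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels) || anyNA(scores)) {
    abort_bad_arg("`scores` must match `labels` in length and contain no NA.",
                  "fmikeys_validation_error")
  }
  interval <- c(NA_real_, NA_real_)
  if (ci) interval <- bootstrap_auc_ci(scores, labels, n_bootstrap, seed)
  structure(
    list(auc = auc_stat(scores, labels),
         ci_low = interval[1], ci_high = interval[2],
         operating_points = roc_points(scores, labels),
         n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
         n_bootstrap = if (ci) n_bootstrap else 0L,
         seed = seed, ci_method = "percentile"),
    class = "fmi_roc"
  )
}

#' @export
print.fmi_roc <- function(x, ...) {
  cat(sprintf("<fmi_roc> AUC %.3f", x$auc))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (95%% CI %.3f-%.3f, %d bootstraps)", x$ci_low, x$ci_high,
                x$n_bootstrap))
  }
  cat(sprintf("; %d positives / %d negatives\n", x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.fmi_roc <- function(x, ...) x$operating_points

#' @export
glance.fmi_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_pos = x$n_pos, n_neg = x$n_neg, n_bootstrap = x$n_bootstrap)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples subjects with replacement; degenerate resamples containing a
#' single class are redrawn (and counted). The 2.5/97.5 percentiles of the
#' resampled AUCs form the interval.
#'
#' @inheritParams roc_auc
#' @return Numeric `c(ci_low, ci_high)`, with attribute `n_redrawn`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_bootstrap = 1000, seed = 1L) {
  labels <- check_labels(labels)
  n <- length(scores)
  with_seed(as.integer(seed), {
    aucs <- numeric(n_bootstrap)
    redrawn <- 0L
    for (b in seq_len(n_bootstrap)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
        redrawn <- redrawn + 1L
      }
      aucs[b] <- auc_stat(scores[idx], labels[idx])
    }
    ci <- unname(stats::quantile(aucs, c(0.025, 0.975), type = 7))
    attr(ci, "n_redrawn") <- redrawn
    ci
  })
}

#' Sensitivity at fixed specificity levels
#'
#' For each target level, the decision threshold is the one whose
#' specificity is the smallest value still at or above the target (no
#' interpolation, so the operating point is exactly reproducible); the
#' sensitivity there is reported with a percentile bootstrap CI. An
#' unattainable target (maximum specificity below it) yields a flagged row
#' rather than an error.
#'
#' @inheritParams roc_auc
#' @param targets Specificity levels to satisfy (default 0.70/0.80/0.90).
#' @return A tibble: `specificity_target`, `threshold`, `specificity`,
#'   `sensitivity`, `ci_low`, `ci_high`, `attained`.
#' @export
sensitivity_at_specificity <- function(scores, labels,
                                       targets = c(0.70, 0.80, 0.90),
                                       n_bootstrap = 1000, seed = 1L) {
  labels <- check_labels(labels)
  pick <- function(sc, lb, target) {
    # thresholds are searched over the observed predictions (plus the
    # all-positive endpoint); the degenerate call-nobody-positive threshold
    # is not an admissible operating point, so a target can be unattainable
    pts <- roc_points(sc, lb)
    pts <- pts[is.finite(pts$threshold) | pts$threshold == -Inf, , drop = FALSE]
    ok <- pts[pts$specificity >= target, , drop = FALSE]
    if (nrow(ok) == 0) {
      return(list(threshold = NA_real_, specificity = NA_real_,
                  sensitivity = NA_real_, attained = FALSE))
    }
    best_spec <- min(ok$specificity)
    at <- ok[ok$specificity == best_spec, , drop = FALSE]
    at <- at[which.max(at$sensitivity), , drop = FALSE]
    list(threshold = at$threshold, specificity = at$specificity,
         sensitivity = at$sensitivity, attained = TRUE)
  }
  boot_sens <- with_seed(derive_seed(seed, "sens_spec"), {
    n <- length(scores)
    sapply(seq_len(n_bootstrap), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
      }
      vapply(targets, function(tg) pick(scores[idx], labels[idx], tg)$sensitivity,
             numeric(1))
    })
  })
  if (is.null(dim(boot_sens))) boot_sens <- matrix(boot_sens, nrow = 1)
  rows <- lapply(seq_along(targets), function(i) {
    p <- pick(scores, labels, targets[i])
    bs <- boot_sens[i, ]
    bs <- bs[!is.na(bs)]
    tibble::tibble(
      specificity_target = targets[i],
      threshold = p$threshold,
      specificity = p$specificity,
      sensitivity = p$sensitivity,
      ci_low = if (length(bs)) unname(stats::quantile(bs, 0.025, type = 7)) else NA_real_,
      ci_high = if (length(bs)) unname(stats::quantile(bs, 0.975, type = 7)) else NA_real_,
      attained = p$attained
    )
  })
  dplyr::bind_rows(rows)
}

#' Scenario evaluation report
#'
#' Reproduces the structure of the three screening test scenarios on any
#' cohort:
#' * `T1` — clinically examined cohort: Pearson correlation of each index
#'   with its clinical item (dRSi~22, dAFSi~23, dBSi~31) plus PD-vs-HC ROC
#'   analyses;
#' * `T2` — de novo screening: ROC analyses restricted to drug-naive PD
#'   (`de_novo == 1`) vs all HC;
#' * `T3` — self-reported cohort: ROC analyses against the (self-reported)
#'   group label only.
#'
#' @param indices An index tibble from [compute_indices()].
#' @param manifest A manifest tibble ([read_manifest()]); `T1` requires the
#'   `updrs_22`/`updrs_23`/`updrs_31` columns, `T2` the `de_novo` column.
#' @param scenario `"T1"`, `"T2"` or `"T3"`.
#' @param n_bootstrap Bootstrap resamples for CIs (default 1000).
#' @param seed Seed for all bootstraps (default 1).
#' @return An object of class `fmi_report`: per-index ROC objects and
#'   sensitivity tables, correlations (T1 only), and metadata. `tidy()`
#'   flattens the AUCs, CIs and correlations into one tibble.
#' @export
scenario_report <- function(indices, manifest, scenario = c("T1", "T2", "T3"),
                            n_bootstrap = 1000, seed = 1L) {
  scenario <- match.arg(scenario)
  dat <- dplyr::inner_join(indices, manifest, by = "subject_id")
  if (nrow(dat) == 0) {
    abort_bad_arg("No overlap between indices and manifest subjects.",
                  "fmikeys_validation_error")
  }
  items <- c(dRSi = "updrs_22", dAFSi = "updrs_23", dBSi = "updrs_31")
  if (scenario == "T1") {
    missing <- setdiff(unname(items), names(dat))
    if (length(missing)) {
      abort_bad_arg(sprintf("Scenario T1 requires manifest column(s): %s.",
                            paste(missing, collapse = ", ")),
                    "fmikeys_validation_error")
    }
  }
  if (scenario == "T2") {
    if (!"de_novo" %in% names(dat)) {
      abort_bad_arg("Scenario T2 requires manifest column: de_novo.",
                    "fmikeys_validation_error")
    }
    dat <- dat[dat$group == "HC" | dat$de_novo == 1, , drop = FALSE]
  }
  labels <- as.integer(dat$group == "PD")

  correlations <- NULL
  if (scenario == "T1") {
    correlations <- dplyr::bind_rows(lapply(names(items), function(nm) {
      keep <- !is.na(dat[[items[[nm]]]])
      pc <- pearson_correlation(dat[[nm]][keep], dat[[items[[nm]]]][keep])
      pc$index <- nm
      pc$item <- sub("updrs_", "", items[[nm]])
      pc
    }))
  }
  roc <- lapply(names(items), function(nm) {
    roc_auc(dat[[nm]], labels, ci = TRUE, n_bootstrap = n_bootstrap,
            seed = derive_seed(seed, "roc", nm))
  })
  names(roc) <- names(items)
  sens <- dplyr::bind_rows(lapply(names(items), function(nm) {
    s <- sensitivity_at_specificity(dat[[nm]], labels,
                                    n_bootstrap = n_bootstrap,
                                    seed = derive_seed(seed, "sens", nm))
    s$index <- nm
    s
  }))
  structure(
    list(scenario = scenario, n_subjects = nrow(dat),
         n_pos = sum(labels), n_neg = sum(labels == 0L),
         correlations = correlations, roc = roc, sensitivity = sens,
         n_bootstrap = n_bootstrap, seed = seed),
    class = "fmi_report"
  )
}

#' @export
print.fmi_report <- function(x, ...) {
  cat(sprintf("<fmi_report> scenario %s: %d subjects (%d PD / %d HC)\n",
              x$scenario, x$n_subjects, x$n_pos, x$n_neg))
  for (nm in names(x$roc)) {
    r <- x$roc[[nm]]
    cat(sprintf("  %-5s AUC %.3f (95%% CI %.3f-%.3f)\n", nm, r$auc, r$ci_low, r$ci_high))
  }
  if (!is.null(x$correlations)) {
    for (i in seq_len(nrow(x$correlations))) {
      cat(sprintf("  %-5s ~ item %s: r = %.3f (p = %.2g)\n",
                  x$correlations$index[i], x$correlations$item[i],
                  x$correlations$r[i], x$correlations$p_value[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.fmi_report <- function(x, ...) {
  out <- dplyr::bind_rows(lapply(names(x$roc), function(nm) {
    g <- glance(x$roc[[nm]])
    g$index <- nm
    g
  }))
  if (!is.null(x$correlations)) {
    out <- dplyr::left_join(out,
                            dplyr::select(x$correlations, "index", "r", "p_value"),
                            by = "index")
  }
  out$scenario <- x$scenario
  dplyr::select(out, "scenario", "index", dplyr::everything())
}

#' @export
glance.fmi_report <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, n_subjects = x$n_subjects,
                 n_pos = x$n_pos, n_neg = x$n_neg,
                 best_auc = max(vapply(x$roc, `[[`, numeric(1), "auc")),
                 n_bootstrap = x$n_bootstrap)
}
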