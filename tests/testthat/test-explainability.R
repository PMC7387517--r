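# A hand-built linear "hybrid" model: flatten + single dense layer with
# chosen weights, wrapped in the fitted-model class so the saliency path
# sees a differentiable stack.
linear_model <- function(w) {
  dense <- fmikeys:::layer_dense(200L, 1L)
  dense$W <- matrix(w, 1L, 200L)
  dense$b <- 0
  structure(list(layers = list(fmikeys:::layer_flatten(), dense),
                 index_name = "dBSi", target_item = 31L),
            class = "fmi_hybrid")
}

# flatten order of a (2, 100) input: channel fastest — ht at odd positions,
# ft at even positions.
ht_pos <- seq(1, 199, by = 2)
ft_pos <- seq(2, 200, by = 2)

test_that("saliency is |w| for a linear model and zero on ignored channels", {
  withr::local_seed(21)
  w <- rnorm(200)
  w[ft_pos] <- 0  # model structurally ignores the FT channel
  m <- linear_model(w)
  input <- matrix(runif(200, 0.05, 0.5), 2, 100,
                  dimnames = list(c("ht", "ft"), NULL))
  sal <- saliency_map(m, input)
  expect_equal(dim(sal$values), c(2, 100))
  expect_identical(unname(sal$values["ft", ]), rep(0, 100))
  # analytic gradient oracle: |w| / max|w|
  expect_equal(unname(sal$values["ht", ]),
               abs(w[ht_pos]) / max(abs(w[ht_pos])))
  expect_equal(max(sal$values), 1)

  # constant-output model: identically zero map (no normalization blow-up)
  zero <- saliency_map(linear_model(rep(0, 200)), input)
  expect_identical(unname(zero$values), matrix(0, 2, 100))

  expect_error(saliency_map(structure(list(), class = "lm"), input),
               class = "fmikeys_unsupported_model_error")
})

test_that("saliency of a trained model is a normalized 2 x 100 map with padding flags", {
  fx <- fixture_pipeline()
  row <- fx$inputs[which(fx$inputs$n_real < 100)[1], ]
  sal <- saliency_map(fx$model31, row)
  expect_equal(dim(sal$values), c(2, 100))
  expect_true(all(sal$values >= 0 & sal$values <= 1))
  expect_equal(max(sal$values), 1)
  d <- tidy(sal)
  expect_equal(sum(d$padded), 2 * (100 - row$n_real))
})

test_that("the ON/OFF trapezoid is exact at plateaus and transition midpoints", {
  sch <- onoff_schedule(intake_times = c(9, 15), on_duration = 120,
                        transition = 30)
  gt <- build_onoff_ground_truth(sch, resolution_min = 1)
  val_at <- function(h) gt$value[which.min(abs(gt$time_hours - h))]
  expect_equal(val_at(10), 1)       # mid-ON plateau
  expect_equal(val_at(13), 0)       # OFF plateau
  expect_equal(val_at(8.75), 0.5)   # 15 min into the 30-min rise
  expect_equal(val_at(11.25), 0.5)  # 15 min into the fall
  expect_true(all(gt$value >= 0 & gt$value <= 1))
  # continuity: one-minute steps never jump more than the transition slope
  expect_lt(max(abs(diff(gt$value))), 1 / 30 + 1e-9)
  # slope is zero outside transitions
  flat <- gt$time_hours > 12.1 & gt$time_hours < 14.4
  expect_true(all(diff(gt$value[flat]) == 0))

  expect_warning(
    build_onoff_ground_truth(onoff_schedule(c(9, 10), on_duration = 180)),
    regexp = "Overlap"
  )
})

test_that("hourly medians use absolute values and skip empty hours", {
  tt <- function(h, m = 0) as.POSIXct(sprintf("2020-03-01 %02d:%02d:00", h, m),
                                      tz = "UTC")
  preds <- tibble::tibble(
    start_time = c(tt(9), tt(10, 1), tt(10, 2), tt(10, 3), tt(13)),
    prediction = c(0.7, -1, 2, 3, 1.2)
  )
  s <- hourly_median_index(preds)
  expect_equal(s$hour, c(9L, 10L, 13L))            # 11/12 missing, not zero
  expect_equal(s$median_index[s$hour == 9], 0.7)   # median of one
  expect_equal(s$median_index[s$hour == 10], 2)    # |-1|,2,3 -> 2
  # invariant to within-hour permutation
  perm <- preds[c(4, 1, 3, 5, 2), ]
  expect_equal(hourly_median_index(perm), s)
  # signed aggregation when asked
  expect_equal(hourly_median_index(preds, absolute = FALSE)$median_index[2], 2)
  expect_error(hourly_median_index(preds[0, ]), class = "fmikeys_validation_error")
})

test_that("the ON/OFF correlation recovers perfect (anti-)alignment", {
  sch <- onoff_schedule(intake_times = c(9, 15), on_duration = 120)
  gt <- build_onoff_ground_truth(sch)
  gt_hour <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(gt, hour = floor(time_hours)), hour),
    v = mean(value), .groups = "drop"
  )
  series <- tibble::tibble(hour = gt_hour$hour, median_index = gt_hour$v,
                           n_sessions = 1L)
  expect_equal(onoff_correlation(series, gt)$r, 1)
  anti <- series
  anti$median_index <- 1 - anti$median_index
  expect_equal(onoff_correlation(anti, gt)$r, -1)
  expect_error(onoff_correlation(series[1:2, ], gt),
               class = "fmikeys_validation_error")
})
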