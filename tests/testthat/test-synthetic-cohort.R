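test_that("cohort shape, group counts and seeded determinism hold", {
  cc <- cohort_config(n_hc = 17, n_pd = 22, n_sessions_per_subject = 2, seed = 9)
  co <- sample_cohort(cc)
  expect_equal(nrow(co$subjects), 39)
  expect_equal(sum(co$subjects$group == "HC"), 17)
  expect_equal(sum(co$subjects$group == "PD"), 22)
  expect_equal(nrow(co$sessions), 39 * 2)
  expect_equal(sum(co$subjects$de_novo), 9)

  # HC latent severities near zero, PD spread over the item scale
  expect_true(all(co$subjects$latent_22[co$subjects$group == "HC"] <= 1))
  expect_true(all(co$subjects$latent_22 >= 0 & co$subjects$latent_22 <= 4))
  expect_identical(co$subjects$updrs_23, round(co$subjects$latent_23))

  co2 <- sample_cohort(cc)
  expect_identical(co$subjects, co2$subjects)
  expect_identical(co$sessions$events, co2$sessions$events)

  expect_error(cohort_config(n_hc = 0, n_pd = 5, seed = 1),
               class = "fmikeys_config_error")
  expect_error(cohort_config(n_hc = 5, n_pd = 5), class = "fmikeys_config_error")
})

test_that("typing dynamics grow slower and more dispersed with severity", {
  cc <- cohort_config(seed = 1, p_longpress = 0, p_pause = 0, p_rollover = 0)
  stats_at <- function(sev) {
    withr::with_seed(500 + round(10 * sev), {
      ht <- c(); ft <- c()
      for (i in 1:200) {
        ev <- fmikeys:::sample_session_events(cc, sev)
        ht <- c(ht, ev$release - ev$press)
        if (nrow(ev) > 1) ft <- c(ft, ev$press[-1] - ev$release[-nrow(ev)])
      }
      c(mht = mean(ht), sht = sd(ht), mft = mean(ft), sft = sd(ft))
    })
  }
  grid <- t(vapply(c(0, 1, 2, 3, 4), stats_at, numeric(4)))
  for (j in 1:4) expect_true(all(diff(grid[, j]) > 0))
})

test_that("log-HT moments match the configured log-normal within 3 SE", {
  cc <- cohort_config(seed = 1, p_longpress = 0, p_pause = 0, p_rollover = 0)
  sev <- 2
  p <- fmikeys:::typing_params(cc, sev)
  lht <- withr::with_seed(77, {
    out <- c()
    for (i in 1:300) {
      ev <- fmikeys:::sample_session_events(cc, sev)
      out <- c(out, log(ev$release - ev$press))
    }
    out
  })
  n <- length(lht)
  expect_lt(abs(mean(lht) - p$ht_meanlog), 3 * p$ht_sdlog / sqrt(n))
  expect_lt(abs(sd(lht) - p$ht_sdlog), 3 * p$ht_sdlog / sqrt(2 * (n - 1)))
})

test_that("generated sessions mostly clear the 40-keystroke validity floor", {
  cc <- cohort_config(n_hc = 10, n_pd = 10, n_sessions_per_subject = 20,
                      session_length_mean = 80, seed = 21)
  co <- sample_cohort(cc)
  feats <- filter_sequences(extract_sequences(co$sessions))
  expect_gt(mean(is_valid_session(feats)), 0.9)
})

test_that("written fixtures round-trip and re-write byte-identically", {
  cc <- cohort_config(n_hc = 3, n_pd = 3, n_sessions_per_subject = 3, seed = 4)
  co <- sample_cohort(cc)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(co, d2)
  man <- read_manifest(file.path(d1, "manifest.csv"))
  expect_equal(nrow(man), 6)
  back <- read_sessions(file.path(d1, "sessions"))
  expect_equal(nrow(back), nrow(co$sessions))
  i <- match(co$sessions$session_id, back$session_id)
  expect_identical(back$events[i], co$sessions$events)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the ON/OFF day modulates severity by the trapezoid envelope", {
  cc <- cohort_config(n_hc = 1, n_pd = 1, n_sessions_per_subject = 1, seed = 2)
  co <- sample_cohort(cc)
  pd <- co$subjects[co$subjects$group == "PD", ]
  sch <- onoff_schedule(intake_times = c(9, 15), on_duration = 180,
                        transition = 30, off_severity_multiplier = 1.6)
  day <- sample_onoff_day(pd, sch, cc, n_sessions = 300, seed = 5)
  hours <- as.numeric(day$start_time -
                        as.POSIXct("2020-03-01 00:00:00", tz = "UTC"),
                      units = "hours")
  env <- fmikeys:::onoff_envelope(sch, hours)
  expect_equal(day$effective_severity,
               pd$latent_motor * (1.6 - 0.6 * env), tolerance = 1e-6)
  # mid-ON sessions carry the unmodulated severity, full-OFF the inflated one
  mid_on <- hours > 10 & hours < 11.5
  full_off <- hours > 19.5
  expect_true(all(abs(day$effective_severity[mid_on] - pd$latent_motor) < 1e-9))
  expect_true(all(abs(day$effective_severity[full_off] - 1.6 * pd$latent_motor) < 1e-9))

  day2 <- sample_onoff_day(pd, sch, cc, n_sessions = 300, seed = 6)
  expect_false(identical(day$events, day2$events))

  hc <- co$subjects[co$subjects$group == "HC", ]
  expect_error(sample_onoff_day(hc, sch, cc, seed = 1),
               class = "fmikeys_validation_error")
})
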