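test_that("session files round-trip bit-exactly and come back sorted", {
  withr::local_seed(42)
  ev <- rand_session_events(25)
  s <- make_session_tbl(ev)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  back <- read_session(file.path(dir, "sess1.json"))
  expect_identical(back$events[[1]]$press, ev$press)
  expect_identical(back$events[[1]]$release, ev$release)
  expect_equal(back$subject_id, "s1")
  expect_equal(back$n_events, 25)

  # a second write of the same session is byte-identical
  dir2 <- withr::local_tempdir()
  write_session(s, dir2)
  expect_identical(readLines(file.path(dir, "sess1.json")),
                   readLines(file.path(dir2, "sess1.json")))

  # unsorted events are returned sorted, count preserved
  shuffled <- ev[sample.int(nrow(ev)), ]
  s2 <- make_session_tbl(shuffled, session_id = "sess2")
  write_session(s2, dir)
  back2 <- read_session(file.path(dir, "sess2.json"))
  expect_equal(back2$n_events, 25)
  expect_identical(back2$events[[1]]$press, sort(ev$press))
})

test_that("malformed session records are rejected with named errors", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.json")

  writeLines('{"subject_id": "a", "events": [[0, 0.1]]}', p)
  expect_error(read_session(p), "start_time", class = "fmikeys_parse_error")

  writeLines('{"subject_id": "a", "start_time": "2020-01-01T10:00:00",
               "events": [[0.5, 0.2]]}', p)
  expect_error(read_session(p), "release", class = "fmikeys_validation_error")

  writeLines('{"subject_id": "a", "start_time": "2020-01-01T10:00:00",
               "events": []}', p)
  expect_error(read_session(p), class = "fmikeys_error")

  expect_error(read_session(file.path(dir, "nope.json")),
               class = "fmikeys_io_error")
})

test_that("hold and flight times follow the defining formulas", {
  s <- make_session_tbl(tibble::tibble(press = c(0, 0.5), release = c(0.1, 0.7)))
  f <- extract_sequences(s)
  expect_equal(f$ht[[1]], c(0.1, 0.2))
  expect_equal(f$ft[[1]], 0.4)
  expect_equal(f$n_keystrokes, 2L)

  # single key-tap: one hold time, zero flight times
  s1 <- make_session_tbl(tibble::tibble(press = 0, release = 0.25))
  f1 <- extract_sequences(s1)
  expect_equal(f1$ht[[1]], 0.25)
  expect_length(f1$ft[[1]], 0)

  # random sessions match the loop-based oracle, and length(ft) = N - 1
  withr::local_seed(7)
  for (n in c(1, 2, 10, 57)) {
    ev <- rand_session_events(n)
    f <- extract_sequences(make_session_tbl(ev))
    o <- oracle_extract(ev)
    expect_equal(f$ht[[1]], o$ht)
    expect_equal(f$ft[[1]], o$ft)
    expect_length(f$ft[[1]], n - 1)
  }
})

test_that("conditional filtering removes long-presses, pauses and rollovers", {
  f <- tibble::tibble(
    session_id = "a", subject_id = "a",
    start_time = as.POSIXct("2020-01-01", tz = "UTC"),
    ht = list(c(0.1, 2.0)), ft = list(3.5), n_keystrokes = 2L
  )
  out <- filter_sequences(f)
  expect_equal(out$ht[[1]], 0.1)
  expect_length(out$ft[[1]], 0)
  expect_equal(out$n_keystrokes, 1L)

  # in-bounds sequences pass through unchanged
  f$ht <- list(c(0.1, 0.2)); f$ft <- list(0.3); f$n_keystrokes <- 2L
  expect_equal(filter_sequences(f)$ht[[1]], c(0.1, 0.2))
  expect_equal(filter_sequences(f)$ft[[1]], 0.3)

  # idempotence and brute-force equivalence on planted violations
  withr::local_seed(13)
  ht <- c(runif(100, 0, 0.45), runif(50, 0.5, 3))[sample.int(150)]
  ft <- c(runif(99, 0, 2.9), runif(50, 3.001, 9), -runif(50, 0.001, 0.1))[sample.int(199)]
  f$ht <- list(ht); f$ft <- list(ft); f$n_keystrokes <- length(ht)
  once <- filter_sequences(f)
  twice <- filter_sequences(once)
  expect_identical(once$ht, twice$ht)
  expect_identical(once$ft, twice$ft)
  o <- oracle_filter(ht, ft)
  expect_equal(once$ht[[1]], o$ht)
  expect_equal(once$ft[[1]], o$ft)
})

test_that("the 40-keystroke validity floor is a sharp boundary", {
  f <- tibble::tibble(
    session_id = c("a", "b", "c"), subject_id = "s",
    start_time = as.POSIXct("2020-01-01", tz = "UTC"),
    ht = list(runif(40, 0, 0.4), runif(39, 0, 0.4), numeric(0)),
    ft = list(runif(39, 0, 2), runif(38, 0, 2), numeric(0)),
    n_keystrokes = c(40L, 39L, 0L)
  )
  expect_equal(is_valid_session(f), c(TRUE, FALSE, FALSE))
  expect_equal(is_valid_session(f, filter_config(min_keystrokes = 39)),
               c(TRUE, TRUE, FALSE))
})

test_that("padding yields 2 x 100 inputs with exact zero tails and splits long sessions", {
  mk <- function(n) tibble::tibble(
    session_id = "a", subject_id = "s",
    start_time = as.POSIXct("2020-01-01", tz = "UTC"),
    ht = list(runif(n, 0.01, 0.4)), ft = list(runif(max(n - 1, 0), 0.01, 2)),
    n_keystrokes = as.integer(n)
  )
  withr::local_seed(3)

  p60 <- pad_to_inputs(mk(60))
  expect_equal(dim(p60$input[[1]]), c(2, 100))
  expect_identical(unname(p60$input[[1]]["ht", 61:100]), rep(0, 40))
  expect_equal(p60$n_real, 60L)

  p100 <- pad_to_inputs(mk(100))
  expect_equal(nrow(p100), 1L)
  expect_true(all(p100$input[[1]]["ht", ] > 0))

  # 130 keystrokes: trailing 30 < 40 dropped
  p130 <- pad_to_inputs(mk(130))
  expect_equal(nrow(p130), 1L)
  expect_equal(p130$n_real, 100L)

  # 150 keystrokes: trailing 50 >= 40 kept as its own segment
  p150 <- pad_to_inputs(mk(150))
  expect_equal(nrow(p150), 2L)
  expect_equal(p150$segment, c(1L, 2L))
  expect_equal(p150$n_real, c(100L, 50L))
  expect_identical(unname(p150$input[[2]]["ht", 51:100]), rep(0, 50))

  expect_error(pad_to_inputs(mk(0)), class = "fmikeys_validation_error")
})
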