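#' Filtering thresholds for keystroke sequences
#'
#' Bundles the conditional-filtering thresholds applied to hold-time (HT) and
#' flight-time (FT) sequences before they are fed to the models, plus the
#' minimum keystroke count for a typing session to count as valid.
#'
#' @param ft_upper_bound Upper bound on flight times, in seconds. FT elements
#'   above it (long pauses between keystrokes) are discarded. Default 3.
#' @param ht_longpress_cutoff Hold times at or above this cutoff, in seconds,
#'   are treated as deliberate long-presses (special keyboard actions such as
#'   accented-character selection) and discarded. Default 0.5, the common
#'   mobile-OS long-press threshold.
#' @param min_keystrokes Minimum number of surviving keystrokes for a session
#'   to be considered valid. Default 40.
#' @return An object of class `filter_config`.
#' @export
#' @examples
#' filter_config()
#' filter_config(ht_longpress_cutoff = 0.8)
filter_config <- function(ft_upper_bound = 3,
                          ht_longpress_cutoff = 0.5,
                          min_keystrokes = 40) {
  stopifnot_scalar_number(ft_upper_bound, "ft_upper_bound")
  stopifnot_scalar_number(ht_longpress_cutoff, "ht_longpress_cutoff")
  stopifnot_scalar_number(min_keystrokes, "min_keystrokes")
  structure(
    list(
      ft_upper_bound = ft_upper_bound,
      ht_longpress_cutoff = ht_longpress_cutoff,
      min_keystrokes = min_keystrokes
    ),
    class = "filter_config"
  )
}

validate_events <- function(events, what = "session") {
  if (!is.data.frame(events) || !all(c("press", "release") %in% names(events))) {
    abort_bad_arg(
      sprintf("%s events must be a data frame with `press` and `release` columns.", what),
      "fmikeys_parse_error"
    )
  }
  if (nrow(events) == 0) {
    abort_bad_arg(sprintf("%s has an empty event list; at least one key-tap is required.", what),
                  "fmikeys_validation_error")
  }
  p <- events$press
  r <- events$release
  if (!is.numeric(p) || !is.numeric(r) || anyNA(p) || anyNA(r) ||
      any(!is.finite(p)) || any(!is.finite(r))) {
    abort_bad_arg(sprintf("%s: press/release timestamps must be finite numbers.", what),
                  "fmikeys_parse_error")
  }
  if (any(p < 0) || any(r < 0)) {
    abort_bad_arg(sprintf("%s: negative timestamps in field press/release.", what),
                  "fmikeys_validation_error")
  }
  if (any(r < p)) {
    abort_bad_arg(sprintf("%s: field release_time is before press_time for %d event(s).",
                          what, sum(r < p)),
                  "fmikeys_validation_error")
  }
  events <- events[order(p), , drop = FALSE]
  if (any(diff(events$press) <= 0)) {
    abort_bad_arg(sprintf("%s: press timestamps are not strictly increasing.", what),
                  "fmikeys_validation_error")
  }
  tibble::as_tibble(events)
}

#' Read a typing-session record file
#'
#' A session record is a JSON object
#' `{"subject_id": ..., "start_time": ISO-8601, "events": [[press_s, release_s], ...]}`
#' with timestamps in seconds since the session start. Events are returned
#' sorted by press time; records violating `release >= press` are rejected.
#'
#' @param path Path to one session JSON file.
#' @return A one-row tibble with columns `session_id` (file stem),
#'   `subject_id`, `start_time` (POSIXct, UTC), `events` (list-column of
#'   tibbles with `press`/`release` in seconds) and `n_events`.
#' @seealso [read_sessions()] to load a directory, [write_session()] for the
#'   inverse operation.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) {
    abort_bad_arg(sprintf("Session file `%s` does not exist.", path),
                  "fmikeys_io_error")
  }
  rec <- tryCatch(
    jsonlite::fromJSON(path, simplifyMatrix = TRUE),
    error = function(e) {
      abort_bad_arg(sprintf("Failed to parse `%s` as session JSON: %s",
                            path, conditionMessage(e)),
                    "fmikeys_parse_error")
    }
  )
  for (field in c("subject_id", "start_time", "events")) {
    if (is.null(rec[[field]])) {
      abort_bad_arg(sprintf("Session file `%s` is missing field `%s`.", path, field),
                    "fmikeys_parse_error")
    }
  }
  ev <- rec$events
  if (is.list(ev) && !is.data.frame(ev)) ev <- do.call(rbind, ev)
  if (!is.matrix(ev) || ncol(ev) != 2) {
    abort_bad_arg(sprintf("Session file `%s`: field `events` must be a list of [press, release] pairs.",
                          path),
                  "fmikeys_parse_error")
  }
  events <- validate_events(
    tibble::tibble(press = as.double(ev[, 1]), release = as.double(ev[, 2])),
    what = sprintf("`%s`", path)
  )
  start <- as.POSIXct(rec$start_time, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (is.na(start)) {
    abort_bad_arg(sprintf("Session file `%s`: field `start_time` is not ISO-8601.", path),
                  "fmikeys_parse_error")
  }
  n_ev <- nrow(events)
  tibble::tibble(
    session_id = sub("\\.json$", "", basename(path)),
    subject_id = as.character(rec$subject_id),
    start_time = start,
    events = list(events),
    n_events = n_ev
  )
}

#' Read every session record in a directory
#'
#' @param dir Directory containing `*.json` session records (see
#'   [read_session()] for the schema).
#' @return A tibble with one row per session, as in [read_session()].
#' @export
read_sessions <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(paths) == 0) {
    abort_bad_arg(sprintf("No session JSON files found under `%s`.", dir),
                  "fmikeys_io_error")
  }
  dplyr::bind_rows(lapply(paths, read_session))
}

#' Write typing sessions back to session-record JSON files
#'
#' Inverse of [read_session()]: timestamps are written at full double
#' precision so that a read/write round trip reproduces the event list
#' exactly.
#'
#' @param sessions A sessions tibble (rows as returned by [read_session()] or
#'   [sample_cohort()]).
#' @param dir Output directory; created if needed. One
#'   `<session_id>.json` file is written per row.
#' @return Invisibly, the paths written.
#' @export
write_session <- function(sessions, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      abort_bad_arg(sprintf("Cannot create directory `%s`.", dir), "fmikeys_io_error")
    }
  }
  paths <- character(nrow(sessions))
  for (i in seq_len(nrow(sessions))) {
    ev <- sessions$events[[i]]
    rec <- list(
      subject_id = sessions$subject_id[i],
      start_time = format(sessions$start_time[i], "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
      events = unname(cbind(ev$press, ev$release))
    )
    paths[i] <- file.path(dir, paste0(sessions$session_id[i], ".json"))
    # 17 significant digits so doubles survive the round trip bit-exactly
    writeLines(
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = I(17)),
      paths[i]
    )
  }
  invisible(paths)
}

#' Derive hold-time and flight-time sequences from typing sessions
#'
#' For a session with press/release timestamps `(t_p[n], t_r[n])`,
#' `n = 1..N`, the hold time is `HT[n] = t_r[n] - t_p[n]` and the flight time
#' is `FT[n] = t_p[n + 1] - t_r[n]`, `n = 1..N-1`: N hold times and N - 1
#' flight times per session, unfiltered.
#'
#' @param sessions A sessions tibble (see [read_sessions()]).
#' @return A tibble with one row per session: `session_id`, `subject_id`,
#'   `start_time`, list-columns `ht` and `ft` (seconds) and `n_keystrokes`
#'   (= `length(ht)`).
#' @seealso [filter_sequences()], [pad_to_inputs()]
#' @export
#' @examples
#' s <- tibble::tibble(
#'   session_id = "s1", subject_id = "a",
#'   start_time = as.POSIXct("2020-01-01 10:00:00", tz = "UTC"),
#'   events = list(tibble::tibble(press = c(0, 0.5), release = c(0.1, 0.7)))
#' )
#' extract_sequences(s)$ht[[1]]  # 0.1 0.2
#' extract_sequences(s)$ft[[1]]  # 0.4
extract_sequences <- function(sessions) {
  if (nrow(sessions) == 0) {
    abort_bad_arg("No sessions to extract sequences from.", "fmikeys_validation_error")
  }
  seqs <- lapply(sessions$events, function(ev) {
    ev <- validate_events(ev)
    n <- nrow(ev)
    list(
      ht = ev$release - ev$press,
      ft = if (n > 1) ev$press[-1] - ev$release[-n] else numeric(0)
    )
  })
  tibble::tibble(
    session_id = sessions$session_id,
    subject_id = sessions$subject_id,
    start_time = sessions$start_time,
    ht = lapply(seqs, `[[`, "ht"),
    ft = lapply(seqs, `[[`, "ft"),
    n_keystrokes = vapply(seqs, function(s) length(s$ht), integer(1))
  )
}

#' Apply conditional filtering to HT/FT sequences
#'
#' Removes, element-wise and order-preserving: hold times at or above the
#' long-press cutoff (deliberate special actions), flight times above the
#' upper bound (pauses, misleading for the model), and negative flight times
#' (rollover typing, where the next key is pressed before the previous
#' release). Neighbouring elements are left untouched; filtering is
#' idempotent. `n_keystrokes` is updated to the surviving hold-time count.
#'
#' @param features A features tibble from [extract_sequences()].
#' @param config A [filter_config()].
#' @return The features tibble with filtered `ht`/`ft` and updated
#'   `n_keystrokes`; sequences may end up empty.
#' @export
filter_sequences <- function(features, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  features$ht <- lapply(features$ht, function(h) h[h < config$ht_longpress_cutoff])
  features$ft <- lapply(features$ft, function(f) f[f >= 0 & f <= config$ft_upper_bound])
  features$n_keystrokes <- vapply(features$ht, length, integer(1))
  features
}

#' Session validity under the minimum-keystroke rule
#'
#' A typing session is valid when its filtered keystroke count reaches the
#' configured floor (default 40).
#'
#' @param features A filtered features tibble ([filter_sequences()]).
#' @param config A [filter_config()].
#' @return A logical vector, one element per row of `features`.
#' @export
is_valid_session <- function(features, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  features$n_keystrokes >= config$min_keystrokes
}

pad_one <- function(x, len = 100) {
  c(x[seq_len(min(length(x), len))], rep(0, max(0, len - length(x))))
}

#' Build fixed-length two-channel model inputs
#'
#' Each valid session becomes one or more 2 x 100 matrices (channel 1 = HT,
#' channel 2 = FT, seconds), zero-padded on the right. Sessions longer than
#' 100 keystrokes are split into consecutive non-overlapping 100-sample
#' segments; a trailing segment is kept only if it alone satisfies the
#' minimum-keystroke rule.
#'
#' @param features A filtered features tibble ([filter_sequences()]).
#' @param config A [filter_config()] (used for the trailing-segment rule).
#' @return A tibble with one row per model input: `session_id`, `subject_id`,
#'   `start_time`, `segment` (1-based), `n_real` (unpadded HT count in the
#'   segment) and `input` (list-column of 2 x 100 matrices with rownames
#'   `ht`, `ft`).
#' @export
pad_to_inputs <- function(features, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  if (nrow(features) == 0 || all(features$n_keystrokes == 0)) {
    abort_bad_arg("No non-empty feature sequences to pad.", "fmikeys_validation_error")
  }
  rows <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    ht <- features$ht[[i]]
    ft <- features$ft[[i]]
    if (length(ht) == 0) next
    n_seg <- ceiling(length(ht) / 100)
    segs <- vector("list", n_seg)
    keep <- logical(n_seg)
    n_real <- integer(n_seg)
    for (s in seq_len(n_seg)) {
      idx <- (100 * (s - 1) + 1):min(100 * s, length(ht))
      n_real[s] <- length(idx)
      # trailing partial segment must stand on its own keystroke count
      keep[s] <- s == 1 || n_real[s] >= config$min_keystrokes
      ft_seg <- ft[idx[idx <= length(ft)]]
      m <- rbind(ht = pad_one(ht[idx]), ft = pad_one(ft_seg))
      segs[[s]] <- m
    }
    if (!any(keep)) next
    rows[[i]] <- tibble::tibble(
      session_id = features$session_id[i],
      subject_id = features$subject_id[i],
      start_time = features$start_time[i],
      segment = which(keep),
      n_real = n_real[keep],
      input = segs[keep]
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort_bad_arg("No segments survived padding.", "fmikeys_validation_error")
  }
  out
}

#' Run the full session-to-input preparation chain
#'
#' Convenience wrapper: extract HT/FT, filter, drop invalid sessions, pad.
#'
#' @inheritParams extract_sequences
#' @inheritParams filter_sequences
#' @return A model-input tibble as from [pad_to_inputs()], restricted to
#'   valid sessions.
#' @export
prepare_inputs <- function(sessions, config = filter_config()) {
  feats <- filter_sequences(extract_sequences(sessions), config)
  feats <- feats[is_valid_session(feats, config), , drop = FALSE]
  if (nrow(feats) == 0) {
    abort_bad_arg("No session passed the validity rule.", "fmikeys_validation_error")
  }
  pad_to_inputs(feats, config)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with one row per subject: `subject_id`, `group`
#' (`HC`/`PD`), `age`, `sex`, UPDRS Part III single-item scores `updrs_22`,
#' `updrs_23`, `updrs_31` (may be empty for self-reported cohorts) and
#' `de_novo` (0/1; drug-naive newly diagnosed PD).
#'
#' @param path Path to the manifest CSV.
#' @return A tibble with the columns above.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort_bad_arg(sprintf("Manifest `%s` does not exist.", path), "fmikeys_io_error")
  }
  man <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           subject_id = readr::col_character(),
                           group = readr::col_character(),
                           .default = readr::col_double()
                         ))
  needed <- c("subject_id", "group")
  missing <- setdiff(needed, names(man))
  if (length(missing)) {
    abort_bad_arg(sprintf("Manifest `%s` is missing column(s): %s.",
                          path, paste(missing, collapse = ", ")),
                  "fmikeys_parse_error")
  }
  if (!all(man$group %in% c("HC", "PD"))) {
    abort_bad_arg("Manifest column `group` must contain only HC or PD.",
                  "fmikeys_validation_error")
  }
  man
}
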