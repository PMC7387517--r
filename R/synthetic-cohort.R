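#' Configuration of the synthetic typing cohort
#'
#' Defines the study conditions of the simulated cohort: group sizes, session
#' lengths, and a planted severity-to-dynamics mechanism. Each subject carries
#' three latent severities on the continuous 0-4 clinical item scale (UPDRS
#' Part III items 22/23/31, pairwise correlated), whose mean drives the typing
#' dynamics: hold times (HT) and flight times (FT) are log-normal with a
#' location that increases linearly with severity and a log-scale dispersion
#' that increases multiplicatively — impaired typists are both slower and less
#' rhythmic. Occasional deliberate long-presses, long pauses and rollover
#' (negative-FT) keystrokes are planted so the conditional filters have real
#' work to do.
#'
#' @param n_hc,n_pd Number of healthy-control and PD subjects. Defaults 17/22,
#'   the shape of a clinically examined smartphone cohort.
#' @param n_sessions_per_subject Typing sessions per subject (default 50).
#' @param session_length_mean,session_length_size Negative-binomial mean and
#'   size for the keystroke count per session (defaults 80 and 12; floor 1).
#' @param ht_location Baseline HT log-normal median, seconds (default 0.10).
#' @param ft_location Baseline FT log-normal median, seconds (default 0.25).
#' @param severity_effect_ht,severity_effect_ft Added seconds of location per
#'   severity unit (defaults 0.02 and 0.05).
#' @param ht_dispersion,ft_dispersion Baseline log-scale sd (defaults 0.25,
#'   0.60).
#' @param dispersion_effect Relative increase of the log-scale sd per severity
#'   unit (default 0.10).
#' @param item_correlation Pairwise latent correlation of the three item
#'   severities (default 0.7).
#' @param de_novo_fraction Fraction of PD subjects flagged de novo
#'   (drug-naive, lowest-severity patients; default 9/22).
#' @param p_longpress,p_pause,p_rollover Per-keystroke probabilities of a
#'   deliberate long-press (HT 0.6-1.5 s), a pause (FT 3-10 s) and a rollover
#'   tap (small negative FT). Defaults 0.02 / 0.01 / 0.01.
#' @param seed Mandatory integer seed; the cohort is a pure function of the
#'   configuration.
#' @return An object of class `cohort_config`.
#' @seealso [sample_cohort()], [write_cohort()]
#' @export
cohort_config <- function(n_hc = 17, n_pd = 22,
                          n_sessions_per_subject = 50,
                          session_length_mean = 80,
                          session_length_size = 12,
                          ht_location = 0.10, ft_location = 0.25,
                          severity_effect_ht = 0.02,
                          severity_effect_ft = 0.05,
                          ht_dispersion = 0.25, ft_dispersion = 0.60,
                          dispersion_effect = 0.10,
                          item_correlation = 0.7,
                          de_novo_fraction = 9 / 22,
                          p_longpress = 0.02, p_pause = 0.01,
                          p_rollover = 0.01,
                          seed) {
  if (missing(seed)) {
    abort_bad_arg("`seed` is mandatory: the cohort must be a pure function of its config.",
                  "fmikeys_config_error")
  }
  for (nm in c("n_hc", "n_pd", "n_sessions_per_subject", "session_length_mean",
               "session_length_size", "ht_location", "ft_location",
               "ht_dispersion", "ft_dispersion")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  for (nm in c("severity_effect_ht", "severity_effect_ft", "dispersion_effect",
               "p_longpress", "p_pause", "p_rollover")) {
    stopifnot_scalar_number(get(nm), nm, positive = FALSE)
  }
  structure(
    list(
      n_hc = as.integer(n_hc), n_pd = as.integer(n_pd),
      n_sessions_per_subject = as.integer(n_sessions_per_subject),
      session_length_mean = session_length_mean,
      session_length_size = session_length_size,
      ht_location = ht_location, ft_location = ft_location,
      severity_effect_ht = severity_effect_ht,
      severity_effect_ft = severity_effect_ft,
      ht_dispersion = ht_dispersion, ft_dispersion = ft_dispersion,
      dispersion_effect = dispersion_effect,
      item_correlation = item_correlation,
      de_novo_fraction = de_novo_fraction,
      p_longpress = p_longpress, p_pause = p_pause, p_rollover = p_rollover,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Log-normal HT/FT parameters at a given (effective) severity.
typing_params <- function(config, severity) {
  list(
    ht_meanlog = log(config$ht_location + config$severity_effect_ht * severity),
    ht_sdlog = config$ht_dispersion * (1 + config$dispersion_effect * severity),
    ft_meanlog = log(config$ft_location + config$severity_effect_ft * severity),
    ft_sdlog = config$ft_dispersion * (1 + config$dispersion_effect * severity)
  )
}

# One session's event list for a given severity; RNG state is the caller's.
sample_session_events <- function(config, severity) {
  n <- max(1L, stats::rnbinom(1, mu = config$session_length_mean,
                              size = config$session_length_size))
  p <- typing_params(config, severity)
  ht <- stats::rlnorm(n, p$ht_meanlog, p$ht_sdlog)
  lp <- stats::runif(n) < config$p_longpress
  ht[lp] <- stats::runif(sum(lp), 0.6, 1.5)
  ft <- stats::rlnorm(n - 1, p$ft_meanlog, p$ft_sdlog)
  if (n > 1) {
    pause <- stats::runif(n - 1) < config$p_pause
    ft[pause] <- stats::runif(sum(pause), 3, 10)
    roll <- stats::runif(n - 1) < config$p_rollover & !pause
    ft[roll] <- -stats::runif(sum(roll), 0.005, 0.02)
  }
  press <- cumsum(c(0, ht[-n] + ft))
  tibble::tibble(press = press, release = press + ht)
}

# Correlated item severities on [lo, hi] via a Gaussian copula.
sample_item_severities <- function(n, rho, lo, hi) {
  if (n == 0) {
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("22", "23", "31"))))
  }
  R <- matrix(rho, 3, 3); diag(R) <- 1
  z <- MASS::mvrnorm(n, mu = rep(0, 3), Sigma = R)
  if (n == 1) z <- matrix(z, 1)
  u <- stats::pnorm(z)
  sev <- lo + u * (hi - lo)
  colnames(sev) <- c("22", "23", "31")
  sev
}

#' Sample a synthetic typing cohort
#'
#' Draws subjects (with latent and rounded clinical item severities,
#' demographics and a de novo flag) and their typing sessions under the
#' planted severity-to-dynamics mechanism of [cohort_config()]. Healthy
#' controls have latent severities in \[0, 0.8\]; PD patients in \[0.3, 4\].
#' Clinical item scores are the latent severities rounded to the 0-4 integer
#' scale, modelling the quantization the clinical scale imposes on the
#' continuous trait. Each subject's randomness comes from a sub-stream keyed
#' by subject index, so enlarging the cohort does not reshuffle existing
#' subjects.
#'
#' @param config A [cohort_config()].
#' @return A list of class `fmi_cohort` with elements
#'   * `subjects`: tibble with `subject_id`, `group`, `age`, `sex`
#'     (1 = male, 0 = female), `updrs_22`/`updrs_23`/`updrs_31`, `de_novo`,
#'     and the latent columns `latent_22`/`latent_23`/`latent_31` and
#'     `latent_motor` (the mean of the three, which drives typing).
#'   * `sessions`: a sessions tibble in the [read_sessions()] layout.
#' @export
#' @examples
#' cohort <- sample_cohort(cohort_config(n_hc = 2, n_pd = 2,
#'                                       n_sessions_per_subject = 3, seed = 1))
#' nrow(cohort$subjects)  # 4
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_hc + config$n_pd
  group <- c(rep("HC", config$n_hc), rep("PD", config$n_pd))
  subject_id <- sprintf("S%03d_%s", seq_len(n), group)

  subjects <- with_seed(derive_seed(config$seed, "subjects"), {
    sev_hc <- sample_item_severities(config$n_hc, config$item_correlation, 0, 0.8)
    sev_pd <- sample_item_severities(config$n_pd, config$item_correlation, 0.3, 4)
    sev <- rbind(sev_hc, sev_pd)
    age <- round(ifelse(group == "HC", stats::rnorm(n, 54.6, 9.4),
                        stats::rnorm(n, 58.6, 8.4)))
    age <- pmin(pmax(age, 30), 85)
    sex <- as.integer(stats::runif(n) < ifelse(group == "HC", 0.59, 0.73))
    tibble::tibble(
      subject_id = subject_id, group = group, age = age, sex = sex,
      latent_22 = sev[, "22"], latent_23 = sev[, "23"], latent_31 = sev[, "31"],
      latent_motor = rowMeans(sev),
      updrs_22 = round(sev[, "22"]), updrs_23 = round(sev[, "23"]),
      updrs_31 = round(sev[, "31"])
    )
  })
  # de novo = the drug-naive, mildest patients
  n_denovo <- round(config$de_novo_fraction * config$n_pd)
  pd_rank <- rank(subjects$latent_motor[subjects$group == "PD"], ties.method = "first")
  subjects$de_novo <- 0L
  subjects$de_novo[subjects$group == "PD"][pd_rank <= n_denovo] <- 1L

  base_date <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC")
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    sessions[[i]] <- with_seed(derive_seed(config$seed, "sessions", i), {
      k <- config$n_sessions_per_subject
      day <- rep(seq_len(ceiling(k / 4)), each = 4)[seq_len(k)]
      hour <- sort(stats::runif(k, 8, 22))
      evs <- lapply(seq_len(k), function(j) {
        sample_session_events(config, subjects$latent_motor[i])
      })
      tibble::tibble(
        session_id = sprintf("%s_sess%04d", subject_id[i], seq_len(k)),
        subject_id = subject_id[i],
        start_time = base_date + ((day - 1) * 24 + hour) * 3600,
        events = evs,
        n_events = vapply(evs, nrow, integer(1))
      )
    })
  }
  structure(
    list(subjects = subjects, sessions = dplyr::bind_rows(sessions),
         config = config),
    class = "fmi_cohort"
  )
}

#' Write a sampled cohort to disk in the session-record layout
#'
#' Emits `manifest.csv` (one row per subject; clinical and latent columns)
#' and a `sessions/` directory of per-session JSON records — exactly the
#' layout the keystroke I/O functions consume. Writing is deterministic:
#' re-writing the same cohort yields byte-identical files.
#'
#' @param cohort An `fmi_cohort` from [sample_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fmi_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) {
      abort_bad_arg(sprintf("Cannot create directory `%s`.", dir), "fmikeys_io_error")
    }
  }
  readr::write_csv(cohort$subjects, file.path(dir, "manifest.csv"))
  write_session(cohort$sessions, file.path(dir, "sessions"))
  invisible(dir)
}

#' Medication ON/OFF schedule
#'
#' Describes a PD patient's levodopa intake pattern over the waking day. Each
#' intake opens an ON phase of `on_duration` minutes starting at the intake
#' time, with linear transitions of `transition` minutes before and after the
#' phase; outside ON phases the patient is OFF.
#'
#' @param intake_times Intake times in hours of day (e.g. `c(8, 14, 20)`).
#' @param on_duration ON-phase duration in minutes (default 180).
#' @param transition Transition duration in minutes (default 30).
#' @param window Analysis day window in hours, default `c(8, 22)`.
#' @param off_severity_multiplier Multiplier (> 1) applied to the latent
#'   severity during full OFF (default 1.6).
#' @return An object of class `onoff_schedule`.
#' @export
onoff_schedule <- function(intake_times, on_duration = 180, transition = 30,
                           window = c(8, 22), off_severity_multiplier = 1.6) {
  stopifnot_scalar_number(on_duration, "on_duration")
  stopifnot_scalar_number(transition, "transition")
  if (off_severity_multiplier <= 1) {
    abort_bad_arg("`off_severity_multiplier` must exceed 1 (OFF is worse than ON).",
                  "fmikeys_config_error")
  }
  if (any(intake_times < window[1] | intake_times > window[2])) {
    abort_bad_arg("All `intake_times` must lie within the day window.",
                  "fmikeys_config_error")
  }
  structure(
    list(intake_times = sort(intake_times), on_duration = on_duration,
         transition = transition, window = window,
         off_severity_multiplier = off_severity_multiplier),
    class = "onoff_schedule"
  )
}

# ON/OFF envelope at hours-of-day `t`: 1 on ON plateaus, 0 on OFF plateaus,
# linear over transitions; overlapping trapezoids merge by max.
onoff_envelope <- function(schedule, t) {
  dur <- schedule$on_duration / 60
  trans <- schedule$transition / 60
  env <- rep(0, length(t))
  for (it in schedule$intake_times) {
    rise <- pmin(pmax((t - (it - trans)) / trans, 0), 1)
    fall <- pmin(pmax(((it + dur + trans) - t) / trans, 0), 1)
    env <- pmax(env, pmin(rise, fall))
  }
  env
}

#' Simulate one ON/OFF day of typing for a PD subject
#'
#' Sessions are timestamped across the day window; at each session's start
#' time the subject's effective severity is the latent severity multiplied by
#' the OFF multiplier during OFF, by 1 during ON, and linearly interpolated
#' across the transitions. HT/FT are drawn from the severity mechanism of the
#' cohort config at that effective severity.
#'
#' @param profile A one-row subjects tibble (from [sample_cohort()]; must be
#'   a PD subject) or any list with `subject_id` and `latent_motor`.
#' @param schedule An [onoff_schedule()].
#' @param config A [cohort_config()] providing the typing mechanism.
#' @param n_sessions Number of sessions across the day (default 60).
#' @param seed Integer seed.
#' @param date Calendar date for the timestamps (default `"2020-03-01"`).
#' @return A sessions tibble (as [read_sessions()]) with an extra
#'   `effective_severity` column.
#' @export
sample_onoff_day <- function(profile, schedule, config, n_sessions = 60, seed,
                             date = "2020-03-01") {
  stopifnot(inherits(schedule, "onoff_schedule"), inherits(config, "cohort_config"))
  if (missing(seed)) abort_bad_arg("`seed` is mandatory.", "fmikeys_config_error")
  if (!is.null(profile$group) && !all(profile$group == "PD")) {
    abort_bad_arg("ON/OFF simulation applies to PD subjects.", "fmikeys_validation_error")
  }
  base <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  with_seed(as.integer(seed), {
    hour <- sort(stats::runif(n_sessions, schedule$window[1], schedule$window[2]))
    env <- onoff_envelope(schedule, hour)
    mult <- schedule$off_severity_multiplier -
      (schedule$off_severity_multiplier - 1) * env
    sev <- profile$latent_motor * mult
    evs <- lapply(sev, function(s) sample_session_events(config, s))
    tibble::tibble(
      session_id = sprintf("%s_onoff%04d", profile$subject_id, seq_len(n_sessions)),
      subject_id = profile$subject_id,
      start_time = base + hour * 3600,
      events = evs,
      n_events = vapply(evs, nrow, integer(1)),
      effective_severity = sev
    )
  })
}
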