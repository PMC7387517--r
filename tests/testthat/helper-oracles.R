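# Independent brute-force oracles used to pin expected values. These stay
# loop-based and naive on purpose: they must not share code with the package
# implementations they check.

# HT/FT extraction by explicit element-wise loops over the event list.
oracle_extract <- function(events) {
  n <- nrow(events)
  ht <- numeric(n)
  for (i in seq_len(n)) ht[i] <- events$release[i] - events$press[i]
  ft <- numeric(0)
  if (n > 1) {
    ft <- numeric(n - 1)
    for (i in seq_len(n - 1)) ft[i] <- events$press[i + 1] - events$release[i]
  }
  list(ht = ht, ft = ft)
}

# Element-wise conditional filter.
oracle_filter <- function(ht, ft, ht_cutoff = 0.5, ft_upper = 3) {
  keep_ht <- numeric(0)
  for (v in ht) if (v < ht_cutoff) keep_ht <- c(keep_ht, v)
  keep_ft <- numeric(0)
  for (v in ft) if (v >= 0 && v <= ft_upper) keep_ft <- c(keep_ft, v)
  list(ht = keep_ht, ft = keep_ft)
}

# AUC as the average pairwise concordance, ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive threshold search: among all thresholds whose specificity
# reaches `target`, take the smallest such specificity, then the best
# sensitivity at it.
oracle_sens_at_spec <- function(scores, labels, target) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  th <- c(-Inf, sort(unique(scores)))
  best <- NULL
  for (t in th) {
    spec <- mean(neg < t)
    sens <- mean(pos >= t)
    if (spec >= target) {
      if (is.null(best) || spec < best$spec ||
          (spec == best$spec && sens > best$sens)) {
        best <- list(spec = spec, sens = sens)
      }
    }
  }
  best
}

# Random event list with planted long-presses, pauses and rollover taps.
rand_session_events <- function(n) {
  ht <- stats::rlnorm(n, log(0.12), 0.4)
  lp <- stats::runif(n) < 0.1
  ht[lp] <- stats::runif(sum(lp), 0.5, 2)
  ft <- stats::rlnorm(max(n - 1, 0), log(0.3), 0.6)
  if (n > 1) {
    long <- stats::runif(n - 1) < 0.08
    ft[long] <- stats::runif(sum(long), 3, 8)
    neg <- stats::runif(n - 1) < 0.08 & !long
    ft[neg] <- -stats::runif(sum(neg), 0.001, 0.02)
  }
  press <- cumsum(c(0, if (n > 1) ht[-n] + ft else numeric(0)))
  tibble::tibble(press = press, release = press + ht)
}

make_session_tbl <- function(events, subject_id = "s1", session_id = "sess1",
                             start = "2020-01-01 10:00:00") {
  tibble::tibble(
    session_id = session_id, subject_id = subject_id,
    start_time = as.POSIXct(start, tz = "UTC"),
    events = list(events), n_events = nrow(events)
  )
}
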