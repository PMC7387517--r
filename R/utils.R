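# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a parent seed
#'
#' Every stage of the pipeline draws its randomness from a stage-specific
#' sub-stream keyed off one global seed, so a single integer reproduces a
#' whole run. The derivation is a fixed integer hash kept below 2^31.
#'
#' @param seed Parent integer seed.
#' @param ... One or more integer/character keys naming the sub-stream
#'   (e.g. a stage name and a fold index).
#' @return An integer seed in `[0, 2^31 - 1]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k))
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

abort_bad_arg <- function(msg, class) {
  rlang::abort(msg, class = c(class, "fmikeys_error"))
}

stopifnot_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (positive && x <= 0)) {
    abort_bad_arg(
      sprintf("`%s` must be a single finite%s number, got %s.",
              name, if (positive) " positive" else "",
              paste(format(x), collapse = ", ")),
      "fmikeys_config_error"
    )
  }
  invisible(x)
}

# quantile type 7 (linear interpolation between order statistics) is the
# aggregation rule used throughout; alias so the choice is explicit.
quartiles_linear <- function(x) {
  unname(stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE))
}
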