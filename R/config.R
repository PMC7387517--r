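# Pipeline configuration: one nested list drives every stage; a YAML file
# with the same sections overrides the defaults. Unknown keys are rejected so
# typos cannot silently fall back to defaults.

#' Default pipeline configuration
#'
#' Returns the full nested configuration consumed by [run_pipeline()], with
#' sections `filtering`, `synthetic`, `autoencoder`, `finetune`,
#' `aggregation`, `evaluation` and `onoff`, plus the global `seed` that fans
#' out to per-stage sub-streams. Any entry can be overridden via `...` using
#' nested lists, or from a YAML file via [read_pipeline_config()].
#'
#' @param ... Named nested overrides, e.g.
#'   `synthetic = list(n_hc = 5), seed = 7`.
#' @return A nested list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 7, synthetic = list(n_hc = 5, n_pd = 5))
#' cfg$synthetic$n_hc
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    filtering = list(ft_upper_bound = 3, ht_longpress_cutoff = 0.5,
                     min_keystrokes = 40),
    synthetic = list(
      n_hc = 17, n_pd = 22, n_sessions_per_subject = 50,
      session_length_mean = 80, session_length_size = 12,
      ht_location = 0.10, ft_location = 0.25,
      severity_effect_ht = 0.02, severity_effect_ft = 0.05,
      ht_dispersion = 0.25, ft_dispersion = 0.60, dispersion_effect = 0.10,
      item_correlation = 0.7, de_novo_fraction = 9 / 22,
      p_longpress = 0.02, p_pause = 0.01, p_rollover = 0.01,
      n_pretrain_subjects = 30, n_pretrain_sessions = 40
    ),
    autoencoder = list(kernel_sizes = c(5, 3, 3),
                       filters_per_layer = c(32, 16, 8),
                       pool_layers = c(TRUE, TRUE, FALSE),
                       epochs = 50, batch_size = 64, learning_rate = 1e-3,
                       train_fraction = 0.8),
    finetune = list(head_nodes = 50, n_frozen_conv_layers = NULL,
                    epochs = 50, batch_size = 32, learning_rate = 1e-3),
    aggregation = list(mode = "wild", wild_index = "q50"),
    evaluation = list(scenarios = c("T1", "T2", "T3"), n_bootstrap = 1000),
    onoff = list(intake_times = c(9, 14, 19), on_duration = 180,
                 transition = 30, window = c(8, 22),
                 off_severity_multiplier = 1.6, n_sessions = 60, n_days = 1)
  )
  merged <- merge_config(defaults, list(...), path = "")
  structure(merged, class = "pipeline_config")
}

merge_config <- function(base, override, path) {
  if (length(override) == 0) return(base)
  nms <- names(override)
  if (is.null(nms) || any(nms == "")) {
    abort_bad_arg(sprintf("Config overrides%s must be named.",
                          if (nzchar(path)) paste0(" under `", path, "`") else ""),
                  "fmikeys_config_error")
  }
  unknown <- setdiff(nms, names(base))
  if (length(unknown)) {
    abort_bad_arg(sprintf("Unknown config key%s: %s.",
                          if (length(unknown) > 1) "s" else "",
                          paste0(if (nzchar(path)) paste0(path, ".") else "",
                                 unknown, collapse = ", ")),
                  "fmikeys_config_error")
  }
  for (nm in nms) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], as.list(override[[nm]]),
                                 path = if (nzchar(path)) paste0(path, ".", nm) else nm)
    } else {
      base[nm] <- override[nm]
    }
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file whose sections mirror [pipeline_config()] and merges it
#' over the defaults; unknown keys are rejected with the offending key named.
#'
#' @param path Path to the YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort_bad_arg(sprintf("Config file `%s` does not exist.", path),
                  "fmikeys_io_error")
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  do.call(pipeline_config, user)
}

# Stable content hash (31-polynomial mod a Mersenne prime) of the resolved
# config's deparsed form, for artifact provenance.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
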