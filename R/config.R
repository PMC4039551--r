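# canonical cell-summary column order (mirrors the printed results tables:
# intercept, treatment effect, variance components, ICC, size variance,
# empirical power)
summary_columns <- c(
  "scenario", "strategy", "k0", "k1", "k", "n_reps",
  "beta0_mean", "beta0_lo", "beta0_hi",
  "beta1_mean", "beta1_lo", "beta1_hi",
  "sigma_b2_mean", "sigma_b2_lo", "sigma_b2_hi",
  "sigma_w2_mean", "sigma_w2_lo", "sigma_w2_hi",
  "icc_mean", "icc_lo", "icc_hi",
  "size_variance", "empirical_power", "n_nonconverged")

config_defaults <- function() {
  list(delta = 0.2, sigma_b2 = 0.05, sigma_w2 = 0.95, alpha = 0.05,
       target_power = 0.8, lam = 1, m = 20L, c = 80L, w = 0,
       mu0 = 0, mu1 = NULL,
       scenario = NULL, k0 = 0L, k1 = 0L, k = 0L,
       completer_fraction = NULL, strategy = NULL,
       n_reps = 1000L, seed = 1L, out = NULL)
}

#' Parse and validate a run configuration
#'
#' Builds a validated configuration from package defaults (the 80-cluster,
#' 20-per-cluster, ICC 0.05, effect 0.2 reference design), an optional YAML
#' file of `key: value` pairs, and an optional list of overrides (e.g.
#' command-line flags).  Precedence: overrides > file > defaults.  Unknown
#' keys and constraint violations are reported together, each named.
#'
#' @param file Optional path to a YAML configuration file.
#' @param overrides Optional named list overriding file values.
#' @return An object of class `run_config`: the merged key list plus
#'   `$design` (a validated [trial_design()]) and `$spec` (a [merge_spec()],
#'   or `NULL` when no scenario is set).
#' @examples
#' cfg <- parse_config(overrides = list(scenario = "S1", k0 = 5, k1 = 5))
#' cfg$design$c
#' @export
parse_config <- function(file = NULL, overrides = list()) {
  cfg <- config_defaults()
  known <- names(cfg)
  problems <- character(0)

  take <- function(cfg, vals, origin) {
    bad <- setdiff(names(vals), known)
    if (length(bad))
      problems <<- c(problems, sprintf("unknown %s key(s): %s", origin,
                                       paste(bad, collapse = ", ")))
    for (nm in intersect(names(vals), known)) cfg[[nm]] <- vals[[nm]]
    cfg
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    cfg <- take(cfg, yaml::read_yaml(file), "config-file")
  }
  if (length(overrides)) cfg <- take(cfg, overrides, "override")
  if (length(problems)) stop(paste(problems, collapse = "\n"))

  design <- tryCatch(
    trial_design(delta = cfg$delta, sigma_b2 = cfg$sigma_b2,
                 sigma_w2 = cfg$sigma_w2, alpha = cfg$alpha,
                 target_power = cfg$target_power, lam = cfg$lam,
                 m = cfg$m, c = cfg$c, w = cfg$w),
    error = function(e) { problems <<- c(problems, conditionMessage(e)); NULL })
  spec <- NULL
  if (!is.null(cfg$scenario))
    spec <- tryCatch(
      merge_spec(cfg$scenario, k0 = cfg$k0, k1 = cfg$k1, k = cfg$k,
                 completer_fraction = cfg$completer_fraction,
                 strategy = cfg$strategy),
      error = function(e) { problems <<- c(problems, conditionMessage(e)); NULL })
  if (!(is.numeric(cfg$n_reps) && cfg$n_reps >= 1))
    problems <- c(problems, "'n_reps' must be a positive integer")
  if (length(problems)) stop(paste(problems, collapse = "\n"))

  cfg$design <- design
  cfg$spec <- spec
  cfg$n_reps <- as.integer(cfg$n_reps)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Write and read Monte Carlo summaries as CSV
#'
#' `write_summary()` accepts a data frame from [run_table()], a single
#' `scenario_summary`, or a list of them, and writes one CSV row per cell in
#' a stable column order.  An empty input writes a header-only file with a
#' warning.  `read_summary()` reads it back.
#'
#' @param summaries Summaries to write.
#' @param path Output CSV path.
#' @return `write_summary` returns `path` invisibly; `read_summary` the data
#'   frame.
#' @export
write_summary <- function(summaries, path) {
  if (inherits(summaries, "scenario_summary"))
    summaries <- list(summaries)
  df <- if (is.data.frame(summaries)) summaries
  else do.call(rbind, lapply(summaries, as.data.frame))
  if (is.null(df) || !nrow(df)) {
    warning("no summaries to write; emitting header only")
    df <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(summary_columns))),
      summary_columns)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  utils::read.csv(path)
}
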