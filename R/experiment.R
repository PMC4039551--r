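mc_ci <- function(x) {
  m <- mean(x)
  se <- stats::sd(x) / sqrt(length(x))
  c(mean = m, lo = m - 1.96 * se, hi = m + 1.96 * se)
}

#' Run one Monte Carlo cell: a (scenario, strategy, merge-count) combination
#'
#' For each replicate: simulate a trial from `design`
#' ([generate_trial()]), apply the merges of `spec` ([apply_merges()]),
#' construct the analysis set for `spec$strategy`
#' ([build_analysis_set()]), and fit the random-intercept model
#' ([fit_random_intercept()]).  Replicate `r` uses the RNG substream
#' `substream_seed(master_seed, r)`, so any replicate can be regenerated in
#' isolation and cells sharing a master seed (e.g. the same scenario
#' analysed under different strategies) see identical trials.
#'
#' @param design A [trial_design()].
#' @param spec A [merge_spec()]; use `k0 = k1 = 0` (or `k = 0`) for a
#'   no-merge cell.
#' @param mu0,mu1 True arm means (default 0 and `design$delta`).
#' @param n_reps Number of Monte Carlo replicates (>= 2).
#' @param master_seed Master seed for the cell.
#' @param alpha Significance level for the empirical-power count.
#' @return An object of class `scenario_summary`: Monte Carlo means with
#'   normal-approximation 95\% intervals (mean +/- 1.96 SE) for `beta0`,
#'   `beta1`, `sigma_b2`, `sigma_w2`, `icc`; `empirical_power` (share of
#'   replicates with Wald p < `alpha`); `mean_size_variance` (mean sample
#'   variance of analysis-cluster sizes); and `n_nonconverged` (replicates
#'   dropped for non-convergence, normally 0).
#' @examples
#' s <- run_cell(trial_design(c = 20L, m = 8L),
#'               merge_spec("S1", k0 = 2, k1 = 2),
#'               n_reps = 10, master_seed = 1)
#' s$empirical_power
#' @export
run_cell <- function(design, spec, mu0 = 0, mu1 = design$delta,
                     n_reps = 1000L, master_seed = 1L, alpha = 0.05) {
  stopifnot(inherits(design, "trial_design"), inherits(spec, "merge_spec"),
            n_reps >= 2)
  stats <- matrix(NA_real_, n_reps, 7,
                  dimnames = list(NULL, c("beta0", "beta1", "sigma_b2",
                                          "sigma_w2", "icc", "sig",
                                          "size_var")))
  n_bad <- 0L
  for (r in seq_len(n_reps)) {
    s <- substream_seed(master_seed, r)
    dat <- generate_trial(design, mu0, mu1, seed = s)
    dat <- apply_merges(dat, spec, seed = substream_seed(s, 1L))
    dat <- build_analysis_set(dat, spec$strategy)
    fit <- fit_random_intercept(dat)
    if (!fit$converged) { n_bad <- n_bad + 1L; next }
    kept <- dat$records[dat$records$analysis_arm != "excluded", ]
    sizes <- tabulate(factor(kept$analysis_cluster))
    stats[r, ] <- c(fit$beta0, fit$beta1, fit$sigma_b2_hat,
                    fit$sigma_w2_hat, fit$icc_hat,
                    as.numeric(significant(fit, alpha)),
                    stats::var(sizes))
  }
  ok <- stats::complete.cases(stats)
  stats <- stats[ok, , drop = FALSE]
  out <- list(scenario = spec$scenario, strategy = spec$strategy,
              k0 = spec$k0, k1 = spec$k1, k = spec$k,
              n_reps = n_reps, n_nonconverged = n_bad,
              beta0 = mc_ci(stats[, "beta0"]),
              beta1 = mc_ci(stats[, "beta1"]),
              sigma_b2 = mc_ci(stats[, "sigma_b2"]),
              sigma_w2 = mc_ci(stats[, "sigma_w2"]),
              icc = mc_ci(stats[, "icc"]),
              empirical_power = mean(stats[, "sig"]),
              n_significant = sum(stats[, "sig"]),
              mean_size_variance = mean(stats[, "size_var"]))
  class(out) <- "scenario_summary"
  out
}

#' @export
print.scenario_summary <- function(x, ...) {
  kdesc <- if (grepl("homog", x$scenario))
    sprintf("k0 = %d, k1 = %d", x$k0, x$k1) else sprintf("k = %d", x$k)
  cat(sprintf("%s / %s (%s), %d replicates (%d non-converged)\n",
              x$scenario, x$strategy, kdesc, x$n_reps, x$n_nonconverged))
  for (f in c("beta0", "beta1", "sigma_b2", "sigma_w2", "icc"))
    cat(sprintf("  %-9s %.3f (%.3f, %.3f)\n", f,
                x[[f]]["mean"], x[[f]]["lo"], x[[f]]["hi"]))
  cat(sprintf("  cluster size variance %.1f;  empirical power %.1f%%\n",
              x$mean_size_variance, 100 * x$empirical_power))
  invisible(x)
}

#' One-row data frame view of a Monte Carlo cell
#' @param x A `scenario_summary`.
#' @param ... Unused.
#' @return A one-row data frame with stable column order.
#' @export
as.data.frame.scenario_summary <- function(x, ...) {
  row <- data.frame(scenario = x$scenario, strategy = x$strategy,
                    k0 = x$k0, k1 = x$k1, k = x$k, n_reps = x$n_reps)
  for (f in c("beta0", "beta1", "sigma_b2", "sigma_w2", "icc")) {
    v <- x[[f]]
    row[[paste0(f, "_mean")]] <- unname(v["mean"])
    row[[paste0(f, "_lo")]] <- unname(v["lo"])
    row[[paste0(f, "_hi")]] <- unname(v["hi"])
  }
  row$size_variance <- x$mean_size_variance
  row$empirical_power <- x$empirical_power
  row$n_nonconverged <- x$n_nonconverged
  row
}

#' Monte Carlo table over a grid of merge counts
#'
#' Replicates a whole results table: for each merge count in `M` (and each
#' strategy), runs [run_cell()].  For homogeneous scenarios the default is
#' the diagonal `k0 = k1 = k`; `grid = "full"` crosses all pairs
#' `(k0, k1) in M x M`.  Heterogeneous scenarios use `k` cross-arm merges.
#' Cells that share a merge count share a master seed across strategies, so
#' every strategy analyses the same simulated trials.
#'
#' @param design A [trial_design()].
#' @param scenario Scenario code (`"S1"`..`"S4"` or long name).
#' @param strategies Character vector of analysis strategies (default: the
#'   scenario's natural set).
#' @param M Merge counts per treatment group.
#' @param n_reps Replicates per cell.
#' @param master_seed Master seed; per-cell seeds are derived from it.
#' @param grid `"diagonal"` (default) or `"full"` (homogeneous only).
#' @param mu0,mu1 True arm means.
#' @param verbose Print per-cell progress to stderr.
#' @return A data frame with one row per cell (see
#'   [as.data.frame.scenario_summary()]).
#' @examples
#' run_table(trial_design(c = 20L, m = 8L), "S1", M = c(0, 2),
#'           n_reps = 5, master_seed = 1)
#' @export
run_table <- function(design, scenario, strategies = NULL,
                      M = c(0L, 1L, 2L, 5L, 10L, 20L),
                      n_reps = 1000L, master_seed = 1L,
                      grid = c("diagonal", "full"),
                      mu0 = 0, mu1 = design$delta, verbose = FALSE) {
  grid <- match.arg(grid)
  probe <- merge_spec(scenario)
  homog <- probe$homogeneous
  if (is.null(strategies))
    strategies <- if (homog) "as_one_cluster" else
      c("assign_control", "assign_intervention", "drop_merged",
        if (probe$scenario == "S4_heter_partial") "completers_only")
  if (grid == "full" && !homog)
    stop("'full' grids of (k0, k1) apply to homogeneous scenarios only")

  cells <- if (homog) {
    if (grid == "diagonal") data.frame(k0 = M, k1 = M)
    else expand.grid(k0 = M, k1 = M)
  } else data.frame(k = M)

  rows <- list()
  for (i in seq_len(nrow(cells))) {
    cell_seed <- substream_seed(master_seed, i)
    for (st in strategies) {
      spec <- if (homog)
        merge_spec(scenario, k0 = cells$k0[i], k1 = cells$k1[i],
                   strategy = st)
      else merge_spec(scenario, k = cells$k[i], strategy = st)
      if (verbose)
        message(sprintf("cell %d/%d strategy %s ...", i, nrow(cells), st))
      s <- run_cell(design, spec, mu0, mu1, n_reps, cell_seed)
      rows[[length(rows) + 1L]] <- as.data.frame(s)
    }
  }
  do.call(rbind, rows)
}
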