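#' Specify a cluster-merge scenario and analysis strategy
#'
#' Four merge scenarios are supported:
#' \describe{
#'   \item{S1 (`"S1_homog_full"`)}{Homogeneous merges: `k0` / `k1` same-arm
#'     pairs per arm combine; every subject completed treatment before the
#'     merge, so outcomes are untouched and only cluster labels change.}
#'   \item{S2 (`"S2_homog_partial"`)}{Homogeneous merges where only a
#'     fraction of each source cluster (default half) completed treatment
#'     before the merge.  Completers keep their original outcome (old
#'     cluster-level error); non-completers have their outcome regenerated
#'     with a single new cluster-level error shared across the merged
#'     cluster.}
#'   \item{S3 (`"S3_heter_full"`)}{Heterogeneous merges: `k` pairs, each of
#'     one control and one intervention cluster, combine; outcomes are
#'     untouched (all subjects completed treatment pre-merge).}
#'   \item{S4 (`"S4_heter_partial"`)}{Heterogeneous merges with partial
#'     completion (default half).  Non-completers are regenerated with the
#'     treatment-group mean implied by the merged cluster's post-merge arm
#'     (which depends on the analysis strategy) and a new shared
#'     cluster-level error.}
#' }
#'
#' Analysis strategies: `as_one_cluster` (homogeneous only: the merged pair
#' is analysed as a single cluster in its original arm), `assign_control` /
#' `assign_intervention` (the whole merged cluster is analysed in that arm),
#' `drop_merged` (merged clusters are excluded), and `completers_only`
#' (non-completers excluded; completers analysed by their original cluster
#' and arm).
#'
#' @param scenario `"S1"`..`"S4"` or the long names above.
#' @param k0,k1 Same-arm pair-merges per arm (homogeneous scenarios).
#' @param k Cross-arm pair-merges (heterogeneous scenarios).
#' @param completer_fraction Fraction of each source cluster that completed
#'   treatment before the merge; fixed at 1 for S1/S3, default 0.5 for
#'   S2/S4.
#' @param strategy Analysis strategy (see above); defaults to
#'   `as_one_cluster` for homogeneous and `drop_merged` for heterogeneous
#'   scenarios.
#' @param noncompleter_cluster_error Error convention for regenerated
#'   non-completers in partial-completion scenarios: `"new_shared"` (default;
#'   one new cluster-level error drawn per merged cluster and shared by all
#'   its non-completers) or `"retain_parent"` (non-completers keep their
#'   original cluster's error and only the mean component and individual
#'   error are refreshed).
#' @return An object of class `merge_spec`.
#' @examples
#' merge_spec("S3", k = 5, strategy = "drop_merged")
#' @export
merge_spec <- function(scenario,
                       k0 = 0L, k1 = 0L, k = 0L,
                       completer_fraction = NULL,
                       strategy = NULL,
                       noncompleter_cluster_error = c("new_shared",
                                                      "retain_parent")) {
  noncompleter_cluster_error <- match.arg(noncompleter_cluster_error)
  long <- c(S1 = "S1_homog_full", S2 = "S2_homog_partial",
            S3 = "S3_heter_full", S4 = "S4_heter_partial")
  if (scenario %in% names(long)) scenario <- long[[scenario]]
  scenario <- match.arg(scenario, unname(long))
  homog <- scenario %in% long[c("S1", "S2")]
  partial <- scenario %in% long[c("S2", "S4")]

  if (is.null(completer_fraction))
    completer_fraction <- if (partial) 0.5 else 1
  if (!partial && completer_fraction != 1)
    stop("scenarios S1/S3 assume all subjects completed treatment ",
         "(completer_fraction = 1)")
  if (completer_fraction < 0 || completer_fraction > 1)
    stop("'completer_fraction' must lie in [0, 1]")

  if (is.null(strategy))
    strategy <- if (homog) "as_one_cluster" else "drop_merged"
  strategy <- match.arg(strategy,
                        c("as_one_cluster", "assign_control",
                          "assign_intervention", "drop_merged",
                          "completers_only"))
  if (strategy == "as_one_cluster" && !homog)
    stop("'as_one_cluster' is only defined for homogeneous merges")
  if (homog && strategy != "as_one_cluster")
    stop("homogeneous scenarios are analysed 'as_one_cluster'")

  k0 <- as.integer(k0); k1 <- as.integer(k1); k <- as.integer(k)
  if (homog && k != 0L)
    stop("use 'k0'/'k1' for homogeneous scenarios, not 'k'")
  if (!homog && (k0 != 0L || k1 != 0L))
    stop("use 'k' for heterogeneous scenarios, not 'k0'/'k1'")
  if (min(k0, k1, k) < 0L) stop("merge counts must be non-negative")

  structure(list(scenario = scenario, homogeneous = homog,
                 k0 = k0, k1 = k1, k = k,
                 completer_fraction = completer_fraction,
                 strategy = strategy,
                 noncompleter_cluster_error = noncompleter_cluster_error),
            class = "merge_spec")
}

new_trial_dataset <- function(records, design, mu0, mu1, seed,
                              mergers = NULL, scenario = NULL,
                              strategy = NULL) {
  structure(list(records = records, design = design, mu0 = mu0, mu1 = mu1,
                 seed = seed, mergers = mergers, scenario = scenario,
                 strategy = strategy),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  ct <- cluster_table(x)
  cat(sprintf("Simulated cluster RCT: %d subjects in %d analysis clusters\n",
              nrow(x$records), nrow(ct)))
  if (!is.null(x$scenario))
    cat(sprintf("  merges applied: %s (%d merged clusters)\n",
                x$scenario, NROW(x$mergers)))
  if (!is.null(x$strategy))
    cat(sprintf("  analysis strategy: %s (%d subjects excluded)\n",
                x$strategy, sum(x$records$analysis_arm == "excluded")))
  invisible(x)
}

#' Per-cluster summary of a simulated trial
#'
#' @param data A `trial_dataset`.
#' @return A data frame with one row per analysis cluster: `cluster`, `arm`
#'   (analysis arm, `"excluded"` if the whole cluster is excluded), `size`
#'   (subjects not excluded), and `merged_from` (comma-separated parent
#'   labels, `NA` for never-merged clusters).
#' @export
cluster_table <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  r <- data$records
  cl <- sort(unique(r$analysis_cluster))
  arm <- vapply(cl, function(x) {
    a <- unique(r$analysis_arm[r$analysis_cluster == x])
    a <- setdiff(a, "excluded")
    if (length(a) == 0L) "excluded" else a[1L]
  }, character(1))
  size <- vapply(cl, function(x)
    sum(r$analysis_cluster == x & r$analysis_arm != "excluded"), integer(1))
  mf <- rep(NA_character_, length(cl))
  if (!is.null(data$mergers) && nrow(data$mergers)) {
    i <- match(data$mergers$cluster, cl)
    mf[i[!is.na(i)]] <- paste(data$mergers$parent0, data$mergers$parent1,
                              sep = ",")[!is.na(i)]
  }
  data.frame(cluster = cl, arm = arm, size = size, merged_from = mf)
}

#' Simulate individual-level data for a two-arm cluster RCT
#'
#' Generates outcomes from the two-level random-intercept model
#' \eqn{Y_{ij} = \mu^{trt} + u_{0j} + \epsilon_{0ij}} with
#' \eqn{u_{0j} \sim N(0, \sigma_b^2)} drawn once per cluster and
#' \eqn{\epsilon_{0ij} \sim N(0, \sigma_w^2)} per subject.  Clusters are
#' equal-sized (`design$m`) and split between arms according to the
#' allocation ratio; the first block of clusters is the control arm.
#'
#' @param design A [trial_design()].
#' @param mu0,mu1 True control / intervention means (default 0 and
#'   `design$delta`).
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   bit for bit.
#' @return A `trial_dataset` whose `records` data frame has columns
#'   `subject_id`, `orig_cluster`, `analysis_cluster`, `orig_arm`,
#'   `analysis_arm` (character, `"0"`/`"1"`/`"excluded"`), `completer`, and
#'   `outcome`.
#' @examples
#' d <- generate_trial(trial_design(c = 6L, m = 4L), seed = 1)
#' head(d$records)
#' @export
generate_trial <- function(design, mu0 = 0, mu1 = design$delta, seed = NULL) {
  stopifnot(inherits(design, "trial_design"))
  if (!is.null(seed)) set.seed(seed)
  arms <- arm_sizes(design$c, design$lam)
  arm_of_cluster <- rep(c(0L, 1L), times = c(arms[["c0"]], arms[["c1"]]))
  n <- design$c * design$m
  u0 <- stats::rnorm(design$c, 0, sqrt(design$sigma_b2))
  eps <- stats::rnorm(n, 0, sqrt(design$sigma_w2))
  cluster <- rep(seq_len(design$c), each = design$m)
  arm <- arm_of_cluster[cluster]
  y <- ifelse(arm == 1L, mu1, mu0) + u0[cluster] + eps
  records <- data.frame(
    subject_id = seq_len(n),
    orig_cluster = cluster,
    analysis_cluster = cluster,
    orig_arm = arm,
    analysis_arm = as.character(arm),
    completer = TRUE,
    outcome = y)
  out <- new_trial_dataset(records, design, mu0, mu1, seed)
  out$u0 <- u0   # cluster effects, kept for the retain-parent regeneration
  out
}

# index of each subject within its original cluster (1..m, generation order)
within_index <- function(records, m) {
  (records$subject_id - 1L) %% m + 1L
}

# sample() that never triggers the 1:x surprise on length-1 vectors
sample_exact <- function(x, n) x[sample.int(length(x), n)]

# regenerate outcomes of non-completers in merged clusters: one new shared
# cluster-level error per merged cluster, fresh individual errors, mean given
# per subject in `mu`
regenerate_noncompleters <- function(data, merged_labels, mu_fun,
                                     retain_parent = FALSE) {
  r <- data$records
  wi <- within_index(r, data$design$m)
  n_keep <- floor(data$spec_completer_fraction * data$design$m)
  for (lab in merged_labels) {
    members <- which(r$analysis_cluster == lab)
    nc <- members[wi[members] > n_keep]
    r$completer[nc] <- FALSE
    u_new <- stats::rnorm(1, 0, sqrt(data$design$sigma_b2))
    if (length(nc)) {
      eps <- stats::rnorm(length(nc), 0, sqrt(data$design$sigma_w2))
      u <- if (retain_parent) data$u0[r$orig_cluster[nc]] else u_new
      r$outcome[nc] <- mu_fun(r[nc, , drop = FALSE]) + u + eps
    }
  }
  data$records <- r
  data
}

#' Apply homogeneous (same-arm) cluster merges
#'
#' In each arm, `k` pairs of clusters that have not yet been involved in any
#' merge are selected uniformly at random and relabelled to a single new
#' analysis cluster.  Under scenario S1 outcomes are untouched.  Under S2
#' only a fraction of each source cluster (the completers, taken as the
#' first `floor(completer_fraction * m)` subjects of the cluster) keep their
#' original outcome; the rest are regenerated with one new shared
#' cluster-level error per merged cluster.
#'
#' @param data A `trial_dataset` from [generate_trial()] (not yet merged).
#' @param spec A [merge_spec()] with a homogeneous scenario.
#' @param seed Optional integer seed for pair selection (and regeneration).
#' @return The merged `trial_dataset`; merged clusters get fresh labels and
#'   the parent labels are recorded in `$mergers`.
#' @export
apply_homogeneous_merges <- function(data, spec, seed = NULL) {
  stopifnot(inherits(data, "trial_dataset"), inherits(spec, "merge_spec"))
  if (!spec$homogeneous) stop("'spec' is not a homogeneous scenario")
  if (!is.null(data$scenario)) stop("merges already applied to this dataset")
  if (!is.null(seed)) set.seed(seed)
  r <- data$records
  next_label <- max(r$orig_cluster) + 1L
  mergers <- NULL
  for (a in c(0L, 1L)) {
    k <- if (a == 0L) spec$k0 else spec$k1
    if (k == 0L) next
    eligible <- unique(r$orig_cluster[r$orig_arm == a])
    if (2L * k > length(eligible))
      stop(sprintf("arm %d has %d clusters; cannot make %d pair-merges",
                   a, length(eligible), k))
    chosen <- sample_exact(eligible, 2L * k)
    p0 <- chosen[seq(1L, 2L * k, by = 2L)]
    p1 <- chosen[seq(2L, 2L * k, by = 2L)]
    new_lab <- next_label + seq_len(k) - 1L
    next_label <- next_label + k
    idx <- match(r$orig_cluster, c(p0, p1))
    hit <- !is.na(idx)
    r$analysis_cluster[hit] <- rep(new_lab, 2L)[idx[hit]]
    mergers <- rbind(mergers,
                     data.frame(cluster = new_lab, parent0 = p0,
                                parent1 = p1, arm = a))
  }
  data$records <- r
  data$mergers <- mergers
  data$scenario <- spec$scenario
  data$spec_completer_fraction <- spec$completer_fraction
  if (spec$scenario == "S2_homog_partial" && !is.null(mergers)) {
    mu0 <- data$mu0; mu1 <- data$mu1
    data <- regenerate_noncompleters(
      data, mergers$cluster,
      mu_fun = function(rec) ifelse(rec$orig_arm == 1L, mu1, mu0),
      retain_parent = spec$noncompleter_cluster_error == "retain_parent")
  }
  data
}

#' Apply heterogeneous (cross-arm) cluster merges
#'
#' `k` merges are formed, each pairing one randomly selected control-arm
#' cluster with one intervention-arm cluster (clusters join at most one
#' merge).  Under S3 outcomes are untouched.  Under S4, non-completers in
#' merged clusters are regenerated: their treatment-group mean follows the
#' merged cluster's post-merge arm under the `assign_control` /
#' `assign_intervention` strategies (and their pre-merge arm under
#' `drop_merged` / `completers_only`, where the records are excluded from
#' analysis anyway), plus one new shared cluster-level error per merged
#' cluster and fresh individual errors.
#'
#' @param data A `trial_dataset` from [generate_trial()] (not yet merged).
#' @param spec A [merge_spec()] with a heterogeneous scenario.
#' @param seed Optional integer seed.
#' @return The merged `trial_dataset`.
#' @export
apply_heterogeneous_merges <- function(data, spec, seed = NULL) {
  stopifnot(inherits(data, "trial_dataset"), inherits(spec, "merge_spec"))
  if (spec$homogeneous) stop("'spec' is not a heterogeneous scenario")
  if (!is.null(data$scenario)) stop("merges already applied to this dataset")
  if (!is.null(seed)) set.seed(seed)
  r <- data$records
  k <- spec$k
  mergers <- NULL
  if (k > 0L) {
    elig0 <- unique(r$orig_cluster[r$orig_arm == 0L])
    elig1 <- unique(r$orig_cluster[r$orig_arm == 1L])
    if (k > min(length(elig0), length(elig1)))
      stop("not enough clusters in an arm for the requested merges")
    p0 <- sample_exact(elig0, k)
    p1 <- sample_exact(elig1, k)
    new_lab <- max(r$orig_cluster) + seq_len(k)
    idx <- match(r$orig_cluster, c(p0, p1))
    hit <- !is.na(idx)
    r$analysis_cluster[hit] <- rep(new_lab, 2L)[idx[hit]]
    mergers <- data.frame(cluster = new_lab, parent0 = p0, parent1 = p1,
                          arm = NA_integer_)
  }
  data$records <- r
  data$mergers <- mergers
  data$scenario <- spec$scenario
  data$spec_completer_fraction <- spec$completer_fraction
  if (spec$scenario == "S4_heter_partial" && !is.null(mergers)) {
    mu0 <- data$mu0; mu1 <- data$mu1
    mu_fun <- switch(spec$strategy,
      assign_control = function(rec) rep(mu0, nrow(rec)),
      assign_intervention = function(rec) rep(mu1, nrow(rec)),
      # excluded from analysis under these strategies; use the pre-merge arm
      # mean so the record stream is deterministic across strategies
      function(rec) ifelse(rec$orig_arm == 1L, mu1, mu0))
    data <- regenerate_noncompleters(
      data, mergers$cluster, mu_fun,
      retain_parent = spec$noncompleter_cluster_error == "retain_parent")
  }
  data
}

#' Apply cluster merges according to a merge specification
#'
#' Convenience dispatcher calling [apply_homogeneous_merges()] or
#' [apply_heterogeneous_merges()] as appropriate.
#'
#' @inheritParams apply_homogeneous_merges
#' @return The merged `trial_dataset`.
#' @export
apply_merges <- function(data, spec, seed = NULL) {
  if (spec$homogeneous) apply_homogeneous_merges(data, spec, seed)
  else apply_heterogeneous_merges(data, spec, seed)
}

#' Construct the analysis set for a given strategy
#'
#' Sets `analysis_arm` (and for `completers_only`, `analysis_cluster`) on
#' every record according to the chosen strategy:
#' \describe{
#'   \item{`as_one_cluster`}{(homogeneous merges only) each merged pair is
#'     analysed as one cluster in its original arm.}
#'   \item{`assign_control` / `assign_intervention`}{every subject of a
#'     merged cluster is analysed in the chosen arm.}
#'   \item{`drop_merged`}{subjects of merged clusters are excluded.}
#'   \item{`completers_only`}{non-completers are excluded; completers are
#'     analysed under their original cluster and arm.}
#' }
#'
#' @param data A `trial_dataset` (merged or not).
#' @param strategy One of the five strategies above.
#' @return The `trial_dataset` with analysis labels set.
#' @export
build_analysis_set <- function(data,
                               strategy = c("as_one_cluster",
                                            "assign_control",
                                            "assign_intervention",
                                            "drop_merged",
                                            "completers_only")) {
  stopifnot(inherits(data, "trial_dataset"))
  strategy <- match.arg(strategy)
  heterogeneous <- !is.null(data$scenario) &&
    grepl("heter", data$scenario, fixed = TRUE)
  if (strategy == "as_one_cluster" && heterogeneous)
    stop("'as_one_cluster' is not available after heterogeneous merges")
  r <- data$records
  r$analysis_arm <- as.character(r$orig_arm)
  merged_labels <- if (is.null(data$mergers)) integer(0) else
    data$mergers$cluster
  in_merged <- r$analysis_cluster %in% merged_labels
  if (strategy == "assign_control") {
    r$analysis_arm[in_merged] <- "0"
  } else if (strategy == "assign_intervention") {
    r$analysis_arm[in_merged] <- "1"
  } else if (strategy == "drop_merged") {
    r$analysis_arm[in_merged] <- "excluded"
  } else if (strategy == "completers_only") {
    r$analysis_cluster <- r$orig_cluster
    r$analysis_arm[!r$completer] <- "excluded"
  }
  data$records <- r
  data$strategy <- strategy
  data
}

#' Write / read a simulated trial as CSV with a JSON metadata sidecar
#'
#' The CSV holds the long-format records
#' (`subject_id,orig_cluster,analysis_cluster,orig_arm,analysis_arm,completer,outcome`);
#' `<path>.meta.json` stores the generating design, scenario, strategy and
#' seed.
#'
#' @param data A `trial_dataset`.
#' @param path Output CSV path.
#' @return `write_trial` returns `path` invisibly; `read_trial` returns a
#'   `trial_dataset`.
#' @export
write_trial <- function(data, path) {
  stopifnot(inherits(data, "trial_dataset"))
  cols <- c("subject_id", "orig_cluster", "analysis_cluster", "orig_arm",
            "analysis_arm", "completer", "outcome")
  utils::write.csv(data$records[, cols], path, row.names = FALSE)
  meta <- list(design = unclass(data$design), mu0 = data$mu0, mu1 = data$mu1,
               seed = data$seed, scenario = data$scenario,
               strategy = data$strategy, mergers = data$mergers)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  records <- utils::read.csv(path, colClasses = c(analysis_arm = "character"))
  meta_path <- paste0(path, ".meta.json")
  design <- NULL; mu0 <- NA; mu1 <- NA; seed <- NULL
  scenario <- NULL; strategy <- NULL; mergers <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    design <- do.call(trial_design, meta$design[
      c("delta", "sigma_b2", "sigma_w2", "alpha", "target_power",
        "lam", "m", "c", "w")])
    mu0 <- meta$mu0; mu1 <- meta$mu1; seed <- meta$seed
    scenario <- meta$scenario; strategy <- meta$strategy
    if (!is.null(meta$mergers) && NROW(meta$mergers))
      mergers <- as.data.frame(meta$mergers)
  }
  new_trial_dataset(records, design, mu0, mu1, seed, mergers, scenario,
                    strategy)
}
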