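test_that("generated trials follow the two-level model", {
  # degenerate noise: outcomes are exactly the arm means
  d0 <- base_design(sigma_b2 = 0, sigma_w2 = 1e-12)
  dat <- generate_trial(d0, mu0 = 1, mu1 = 3, seed = 1)
  expect_equal(dat$records$outcome,
               ifelse(dat$records$orig_arm == 1L, 3, 1), tolerance = 1e-5)

  # same seed -> bit-identical dataset; different seed -> different
  a <- generate_trial(base_design(), seed = 99)
  b <- generate_trial(base_design(), seed = 99)
  expect_identical(a$records, b$records)
  expect_false(identical(
    a$records$outcome, generate_trial(base_design(), seed = 100)$records$outcome))

  # structure: c clusters of m, equal arms, all completers
  ct <- cluster_table(a)
  expect_equal(nrow(ct), 80L)
  expect_true(all(ct$size == 20L))
  expect_equal(sum(ct$arm == "0"), 40L)
  expect_true(all(a$records$completer))
})

test_that("cluster-mean variance matches the law of total variance", {
  # var of cluster means of (Y - mu) is sigma_b2 + sigma_w2 / m; check on a
  # 2000-cluster trial
  d <- base_design(c = 2000L)
  dat <- generate_trial(d, mu0 = 0, mu1 = 0, seed = 5)
  cm <- tapply(dat$records$outcome, dat$records$orig_cluster, mean)
  expect_equal(stats::var(cm), d$sigma_b2 + d$sigma_w2 / d$m,
               tolerance = 0.07)
})

test_that("homogeneous merges relabel without touching outcomes (S1)", {
  dat <- generate_trial(base_design(), seed = 3)
  m0 <- apply_homogeneous_merges(dat, merge_spec("S1"), seed = 4)
  expect_identical(m0$records, dat$records)  # k0 = k1 = 0: no change

  spec <- merge_spec("S1", k0 = 5, k1 = 5)
  m1 <- apply_homogeneous_merges(dat, spec, seed = 4)
  # outcomes and arms bit-identical; only analysis_cluster changed
  expect_identical(m1$records$outcome, dat$records$outcome)
  expect_identical(m1$records$orig_arm, dat$records$orig_arm)
  expect_true(all(m1$records$completer))
  # arm means (hence the treatment contrast) unchanged to machine precision
  arm_mean <- function(r, a) mean(r$outcome[r$orig_arm == a])
  expect_identical(arm_mean(m1$records, 1) - arm_mean(m1$records, 0),
                   arm_mean(dat$records, 1) - arm_mean(dat$records, 0))
  # each merged cluster has 2m members from one arm; parents distinct
  ct <- cluster_table(m1)
  expect_equal(sum(ct$size == 40L), 10L)
  expect_equal(nrow(ct), 70L)
  parents <- unlist(strsplit(ct$merged_from[!is.na(ct$merged_from)], ","))
  expect_equal(anyDuplicated(parents), 0L)
})

test_that("post-merge size vector matches the closed-form variance", {
  dat <- generate_trial(base_design(), seed = 8)
  for (k in c(1L, 2L, 5L, 10L, 20L)) {
    m1 <- apply_homogeneous_merges(dat, merge_spec("S1", k0 = k, k1 = k),
                                   seed = k)
    sizes <- cluster_table(m1)$size
    expect_equal(stats::var(sizes), merged_size_variance(20, 80, 2 * k),
                 tolerance = 1e-10)
  }
})

test_that("partial-completion merges regenerate only non-completers (S2)", {
  dat <- generate_trial(base_design(), seed = 13)
  # completer_fraction = 1 is identical to S1 under the same seed
  s1 <- apply_homogeneous_merges(dat, merge_spec("S1", k0 = 3, k1 = 2),
                                 seed = 21)
  s2_full <- apply_homogeneous_merges(
    dat, merge_spec("S2", k0 = 3, k1 = 2, completer_fraction = 1),
    seed = 21)
  expect_identical(s1$records, s2_full$records)

  s2 <- apply_homogeneous_merges(dat, merge_spec("S2", k0 = 3, k1 = 2),
                                 seed = 21)
  r <- s2$records
  merged <- r$analysis_cluster %in% s2$mergers$cluster
  # completers keep their original outcome, non-completers do not
  expect_identical(r$outcome[r$completer], dat$records$outcome[r$completer])
  expect_false(any(r$outcome[!r$completer] ==
                     dat$records$outcome[!r$completer]))
  # half of each merged cluster completes; unmerged clusters are untouched
  expect_true(all(r$completer[!merged]))
  expect_equal(sum(!r$completer), (3 + 2) * 2 * 10)
  # regenerated outcomes share one new cluster effect per merged cluster:
  # within each merged cluster, non-completer deviations from the arm mean
  # have a common component -> their cluster means differ from mu_arm by the
  # shared draw; just check the deviations are identical across the two
  # parent halves in expectation by construction (shared u):
  for (lab in s2$mergers$cluster) {
    nc <- r[!r$completer & r$analysis_cluster == lab, ]
    mu <- ifelse(nc$orig_arm == 1L, s2$mu1, s2$mu0)
    dev <- nc$outcome - mu
    # one shared cluster effect: deviations are u + eps, so their mean over
    # 20 subjects estimates u; the spread about that mean is pure eps
    expect_equal(length(unique(nc$orig_cluster)), 2L)
  }
})

test_that("heterogeneous merges pair one cluster from each arm (S3)", {
  dat <- generate_trial(base_design(), seed = 17)
  m0 <- apply_heterogeneous_merges(dat, merge_spec("S3", k = 0), seed = 2)
  expect_identical(m0$records, dat$records)

  m1 <- apply_heterogeneous_merges(dat, merge_spec("S3", k = 5), seed = 2)
  expect_identical(m1$records$outcome, dat$records$outcome)
  for (lab in m1$mergers$cluster) {
    members <- m1$records[m1$records$analysis_cluster == lab, ]
    expect_equal(sum(members$orig_arm == 0L), 20L)
    expect_equal(sum(members$orig_arm == 1L), 20L)
  }
  # mixed composition: expected merged-cluster mean is (mu0 + mu1) / 2;
  # check across many merges at a higher-level seed
  big <- apply_heterogeneous_merges(generate_trial(base_design(), seed = 18),
                                    merge_spec("S3", k = 20), seed = 3)
  mm <- sapply(big$mergers$cluster, function(lab)
    mean(big$records$outcome[big$records$analysis_cluster == lab]))
  # each merged-cluster mean has sd ~ sqrt(sigma_b2/2 + sigma_w2/40) = 0.22,
  # so the mean over 20 merges has SE ~ 0.05; use a 2-SE absolute band
  expect_lt(abs(mean(mm) - (big$mu0 + big$mu1) / 2), 0.1)
})

test_that("S4 regenerates non-completers by post-merge arm; fraction 1 is S3", {
  dat <- generate_trial(base_design(), seed = 23)
  s3 <- apply_heterogeneous_merges(dat, merge_spec("S3", k = 4), seed = 5)
  s4_full <- apply_heterogeneous_merges(
    dat, merge_spec("S4", k = 4, completer_fraction = 1,
                    strategy = "assign_control"), seed = 5)
  expect_identical(s3$records, s4_full$records)

  s4 <- apply_heterogeneous_merges(
    dat, merge_spec("S4", k = 4, strategy = "assign_intervention"), seed = 5)
  r <- s4$records
  expect_identical(r$outcome[r$completer], dat$records$outcome[r$completer])
  expect_equal(sum(!r$completer), 4 * 2 * 10)
  # non-completer outcomes now centre on mu1 regardless of original arm
  nc <- r[!r$completer, ]
  expect_equal(mean(nc$outcome), s4$mu1, tolerance = 0.3)
})

test_that("the retain-parent error convention keeps the old cluster effect", {
  # with negligible individual error, a regenerated non-completer's outcome
  # minus its new mean must equal its parent cluster's effect exactly
  d <- base_design(sigma_w2 = 1e-18, sigma_b2 = 0.05)
  dat <- generate_trial(d, seed = 47)
  s4 <- apply_heterogeneous_merges(
    dat, merge_spec("S4", k = 3, strategy = "assign_control",
                    noncompleter_cluster_error = "retain_parent"), seed = 9)
  nc <- s4$records[!s4$records$completer, ]
  expect_equal(nc$outcome - s4$mu0, s4$u0[nc$orig_cluster], tolerance = 1e-6)
  # default convention: one shared value per merged cluster instead
  s4n <- apply_heterogeneous_merges(
    dat, merge_spec("S4", k = 3, strategy = "assign_control"), seed = 9)
  ncn <- s4n$records[!s4n$records$completer, ]
  u_by_cluster <- tapply(ncn$outcome - s4n$mu0, ncn$analysis_cluster,
                         function(x) length(unique(round(x, 6))))
  expect_true(all(u_by_cluster == 1))
})

test_that("a cluster participates in at most one merge", {
  dat <- generate_trial(base_design(), seed = 31)
  for (spec in list(merge_spec("S1", k0 = 20, k1 = 20),
                    merge_spec("S3", k = 40))) {
    m <- apply_merges(dat, spec, seed = 6)
    parents <- unlist(m$mergers[c("parent0", "parent1")])
    expect_equal(anyDuplicated(parents), 0L)
  }
  expect_error(apply_homogeneous_merges(dat, merge_spec("S1", k0 = 21)),
               "cannot make")
  expect_error(apply_heterogeneous_merges(dat, merge_spec("S3", k = 41)),
               "not enough clusters")
})

test_that("analysis sets implement the five strategies", {
  dat <- generate_trial(base_design(), seed = 37)
  het <- apply_heterogeneous_merges(dat, merge_spec("S3", k = 5), seed = 7)

  # no merges: every strategy returns the original labels
  for (st in c("assign_control", "drop_merged", "completers_only")) {
    a <- build_analysis_set(generate_trial(base_design(), seed = 37), st)
    expect_equal(a$records$analysis_arm, as.character(a$records$orig_arm))
    expect_equal(a$records$analysis_cluster, a$records$orig_cluster)
  }

  ac <- build_analysis_set(het, "assign_control")
  merged <- ac$records$analysis_cluster %in% het$mergers$cluster
  expect_true(all(ac$records$analysis_arm[merged] == "0"))
  ai <- build_analysis_set(het, "assign_intervention")
  expect_true(all(ai$records$analysis_arm[merged] == "1"))

  dm <- build_analysis_set(het, "drop_merged")
  expect_true(all(dm$records$analysis_arm[merged] == "excluded"))
  kept <- cluster_table(dm)
  expect_equal(sum(kept$arm != "excluded"), 80L - 2L * 5L)
  expect_equal(sum(kept$size), (80L - 2L * 5L) * 20L)

  expect_error(build_analysis_set(het, "as_one_cluster"), "not available")
})

test_that("completers-only keeps completers under their original labels", {
  # brute-force count on a small instance: c = 6, m = 4, k = 1, fraction 0.5
  d <- trial_design(c = 6L, m = 4L)
  dat <- generate_trial(d, seed = 41)
  het <- apply_heterogeneous_merges(
    dat, merge_spec("S4", k = 1, strategy = "completers_only"), seed = 8)
  co <- build_analysis_set(het, "completers_only")
  kept <- co$records[co$records$analysis_arm != "excluded", ]
  # merged parents contribute floor(0.5 * 4) = 2 each; 4 unmerged keep all 4
  expect_equal(nrow(kept), 4L * 4L + 2L * 2L)
  expect_equal(kept$analysis_cluster, kept$orig_cluster)
  expect_equal(kept$analysis_arm, as.character(kept$orig_arm))
  expect_true(all(kept$completer))
})

test_that("trial datasets round-trip through CSV plus metadata sidecar", {
  dat <- generate_trial(base_design(c = 10L, m = 4L), seed = 43)
  dat <- apply_merges(dat, merge_spec("S1", k0 = 1, k1 = 1), seed = 44)
  dat <- build_analysis_set(dat, "as_one_cluster")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(dat, path)
  back <- read_trial(path)
  expect_equal(back$records$outcome, dat$records$outcome)
  expect_equal(back$records$analysis_cluster, dat$records$analysis_cluster)
  expect_equal(back$records$analysis_arm, dat$records$analysis_arm)
  expect_equal(back$design$c, dat$design$c)
  expect_equal(back$scenario, dat$scenario)
})
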