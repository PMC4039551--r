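# reference design used throughout: 80 clusters of 20, total variance 1,
# ICC 0.05, effect 0.2, two-sided 5% level, 80% planned power
base_design <- function(...) {
  args <- utils::modifyList(
    list(delta = 0.2, sigma_b2 = 0.05, sigma_w2 = 0.95, alpha = 0.05,
         target_power = 0.8, lam = 1, m = 20L, c = 80L, w = 0),
    list(...))
  do.call(trial_design, args)
}

# small design for cheap structural tests
tiny_design <- function(...) base_design(c = 8L, m = 4L, ...)

# explicit post-merge size vector: k clusters of 2m, c - 2k singletons of m
merged_size_vector <- function(m, c, k) c(rep(2 * m, k), rep(m, c - 2 * k))

# one-way ANOVA closed forms for balanced designs with an arm fixed effect:
# MSW from within-cluster residuals, MSB from cluster means about arm means
anova_components <- function(records) {
  r <- records[records$analysis_arm != "excluded", ]
  cl <- factor(r$analysis_cluster)
  n_j <- tabulate(cl)
  stopifnot(length(unique(n_j)) == 1L)   # balanced only
  m <- n_j[1]
  ybar <- as.vector(rowsum(r$outcome, cl)) / n_j
  arm_j <- as.integer(tapply(as.integer(r$analysis_arm), cl, `[`, 1L))
  arm_means <- tapply(ybar, arm_j, mean)
  ssw <- sum(r$outcome^2) - sum(n_j * ybar^2)
  msw <- ssw / (nrow(r) - length(n_j))
  msb <- m * sum((ybar - arm_means[as.character(arm_j)])^2) /
    (length(n_j) - 2)
  sb2 <- max((msb - msw) / m, 0)
  list(sigma_w2 = msw, sigma_b2 = sb2)
}

fit_lmer_reference <- function(records) {
  r <- records[records$analysis_arm != "excluded", ]
  r$arm <- as.integer(r$analysis_arm)
  m <- lme4::lmer(outcome ~ arm + (1 | analysis_cluster), data = r,
                  REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  list(beta0 = unname(lme4::fixef(m)[1]), beta1 = unname(lme4::fixef(m)[2]),
       se_beta1 = sqrt(as.matrix(stats::vcov(m))[2, 2]),
       sigma_b2 = vc$vcov[1], sigma_w2 = vc$vcov[2])
}
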