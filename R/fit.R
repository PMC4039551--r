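#' Fit the two-level random-intercept model by profiled REML
#'
#' Fits \eqn{Y_{ij} = \beta_0 + \beta_1\,\mathrm{arm}_j + u_{0j} +
#' \epsilon_{0ij}} with \eqn{u_{0j} \sim N(0, \sigma_b^2)} and
#' \eqn{\epsilon_{0ij} \sim N(0, \sigma_w^2)} to the analysis set of a
#' simulated trial (records with `analysis_arm == "excluded"` are removed;
#' arm is constant within an analysis cluster under every supported
#' strategy).
#'
#' Estimation profiles the restricted likelihood over the variance ratio
#' \eqn{\theta = \sigma_b^2 / \sigma_w^2}.  Writing \eqn{n_j},
#' \eqn{\bar y_j} for cluster sizes and means, \eqn{w_j = n_j/(1+n_j\theta)}
#' and \eqn{W_g = \sum_{j \in \mathrm{arm}\,g} w_j}, generalised least
#' squares gives \eqn{\hat\beta_0} and \eqn{\hat\beta_1} as weighted arm
#' means of the cluster means, and the profiled \eqn{-2\log L_R} is
#' \deqn{(N-2)\log Q(\theta) + \sum_j \log(1+n_j\theta) + \log(W_0 W_1),}
#' with \eqn{Q(\theta)} the within-cluster sum of squares plus the weighted
#' between-cluster residual sum of squares.  The ratio is optimised on
#' \eqn{[0, \infty)} (boundary \eqn{\hat\sigma_b^2 = 0} allowed) to
#' tolerance 1e-8, then \eqn{\hat\sigma_w^2 = Q/(N-2)} and
#' \eqn{\hat\sigma_b^2 = \hat\theta\,\hat\sigma_w^2}.  On balanced data the
#' estimates coincide with the one-way ANOVA closed forms, and on any data
#' with a mixed-model REML fit (e.g. \pkg{lme4}).
#'
#' The treatment-effect test is a two-sided Wald z test,
#' \eqn{p = 2\Phi(-|\hat\beta_1/\mathrm{se}|)} (normal reference, no
#' small-sample correction).
#'
#' @param data A `trial_dataset` (typically after [build_analysis_set()]),
#'   or a data frame with columns `outcome`, `analysis_cluster`,
#'   `analysis_arm`.
#' @return An object of class `crt_fit`: a list with elements `beta0`,
#'   `beta1`, `se_beta1`, `p_value`, `sigma_b2_hat`, `sigma_w2_hat`,
#'   `icc_hat`, `n_clusters`, `n_subjects`, `converged`.
#' @examples
#' d <- generate_trial(trial_design(), seed = 1)
#' fit <- fit_random_intercept(d)
#' fit$beta1; fit$icc_hat
#' @export
fit_random_intercept <- function(data) {
  r <- if (inherits(data, "trial_dataset")) data$records else data
  r <- r[r$analysis_arm != "excluded", , drop = FALSE]
  if (!nrow(r)) stop("empty analysis set")
  arm_chr <- r$analysis_arm
  if (!all(arm_chr %in% c("0", "1")))
    stop("analysis_arm must be '0', '1' or 'excluded'")

  cl <- factor(r$analysis_cluster)
  J <- nlevels(cl)
  n_j <- tabulate(cl)
  sum_y <- as.vector(rowsum(r$outcome, cl))
  ybar <- sum_y / n_j
  ssw <- sum(r$outcome^2) - sum(n_j * ybar^2)
  # arm is cluster-level under every strategy; verify and reduce
  arm_j <- as.integer(tapply(as.integer(arm_chr), cl, function(a) {
    if (length(unique(a)) > 1L)
      stop("treatment arm varies within an analysis cluster")
    a[1L]
  }))
  if (sum(arm_j == 0L) < 2L || sum(arm_j == 1L) < 2L)
    stop("need at least two analysis clusters per arm")
  N <- nrow(r)

  gls_parts <- function(theta) {
    w <- n_j / (1 + n_j * theta)
    W0 <- sum(w[arm_j == 0L]); W1 <- sum(w[arm_j == 1L])
    b0 <- sum(w[arm_j == 0L] * ybar[arm_j == 0L]) / W0
    mu1 <- sum(w[arm_j == 1L] * ybar[arm_j == 1L]) / W1
    Q <- ssw + sum(w * (ybar - ifelse(arm_j == 1L, mu1, b0))^2)
    list(w = w, W0 = W0, W1 = W1, beta0 = b0, beta1 = mu1 - b0, Q = Q)
  }
  crit <- function(theta) {
    p <- gls_parts(theta)
    (N - 2) * log(p$Q) + sum(log1p(n_j * theta)) + log(p$W0 * p$W1)
  }

  upper <- 5
  converged <- TRUE
  repeat {
    opt <- stats::optimize(crit, c(0, upper), tol = 1e-8)
    if (opt$minimum < upper * 0.99 || upper > 1e3) break
    upper <- upper * 10
  }
  theta <- opt$minimum
  if (upper > 1e3 && theta > upper * 0.99) converged <- FALSE
  # optimize never probes the endpoints themselves: accept the boundary
  # theta = 0 when it does at least as well as the interior candidate
  if (crit(0) <= opt$objective) theta <- 0

  p <- gls_parts(theta)
  sigma_w2 <- p$Q / (N - 2)
  sigma_b2 <- theta * sigma_w2
  se_beta1 <- sqrt(sigma_w2 * (1 / p$W0 + 1 / p$W1))
  z <- p$beta1 / se_beta1
  structure(list(beta0 = p$beta0, beta1 = p$beta1, se_beta1 = se_beta1,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 sigma_b2_hat = sigma_b2, sigma_w2_hat = sigma_w2,
                 icc_hat = if (sigma_b2 + sigma_w2 > 0)
                   sigma_b2 / (sigma_b2 + sigma_w2) else 0,
                 n_clusters = J, n_subjects = N, converged = converged),
            class = "crt_fit")
}

#' @export
print.crt_fit <- function(x, ...) {
  cat("Random-intercept model (profiled REML)\n")
  cat(sprintf("  %d subjects in %d clusters\n", x$n_subjects, x$n_clusters))
  cat(sprintf("  beta0 = %.4f   beta1 = %.4f (se %.4f, Wald p = %.4g)\n",
              x$beta0, x$beta1, x$se_beta1, x$p_value))
  cat(sprintf("  sigma_b2 = %.4f   sigma_w2 = %.4f   ICC = %.4f\n",
              x$sigma_b2_hat, x$sigma_w2_hat, x$icc_hat))
  if (!x$converged) cat("  WARNING: variance-ratio search did not converge\n")
  invisible(x)
}

#' Did the trial show a significant treatment difference?
#'
#' @param fit A `crt_fit`.
#' @param alpha Significance level; the test is `p_value < alpha` (strict).
#' @return Logical.
#' @examples
#' d <- generate_trial(trial_design(), seed = 1)
#' significant(fit_random_intercept(d))
#' @export
significant <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "crt_fit"))
  fit$p_value < alpha
}

#' One-row data frame view of a model fit
#' @param x A `crt_fit`.
#' @param ... Unused.
#' @return A one-row data frame with all fit fields.
#' @export
as.data.frame.crt_fit <- function(x, ...) {
  as.data.frame(unclass(x))
}
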