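#' Specify a two-arm cluster randomised trial design
#'
#' Collects the design parameters of a parallel two-arm cluster randomised
#' controlled trial (cluster RCT) with a continuous outcome: the effect to be
#' detected, the variance components of the two-level outcome model, error
#' rates, the cluster allocation ratio, cluster number and size, and
#' anticipated individual-level attrition.
#'
#' The outcome model is the random-intercept model
#' \deqn{Y_{ij} = \mu^{trt}_{ij} + u_{0j} + \epsilon_{0ij},}
#' with cluster effects \eqn{u_{0j} \sim N(0, \sigma_b^2)} and individual
#' errors \eqn{\epsilon_{0ij} \sim N(0, \sigma_w^2)}.  The intracluster
#' correlation coefficient (ICC) is
#' \eqn{\rho = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)}.
#'
#' @param delta Effect size to detect: difference in arm means, in outcome
#'   units.  Must be non-zero.
#' @param sigma_b2 Between-cluster variance component (>= 0).
#' @param sigma_w2 Within-cluster variance component (> 0).
#' @param alpha Two-sided type I error probability, in (0, 1).
#' @param target_power Planned power \eqn{1 - \beta}, in (0, 1).
#' @param lam Allocation ratio \eqn{\lambda} of clusters between arms
#'   (control : intervention); power is maximal at 1.  Must be positive.
#' @param m Planned number of individuals per cluster (positive integer).
#' @param c Total number of clusters (positive integer; even for an equal
#'   split when `lam = 1`).
#' @param w Anticipated individual-level attrition proportion, in [0, 1).
#'
#' @return An object of class `trial_design`: a list with the arguments plus
#'   the derived total variance `sigma2` and ICC `rho`.
#'
#' @examples
#' d <- trial_design(delta = 0.2, sigma_b2 = 0.05, sigma_w2 = 0.95,
#'                   m = 20, c = 80)
#' d$rho     # 0.05
#' crt_power(d)
#' @export
trial_design <- function(delta = 0.2, sigma_b2 = 0.05, sigma_w2 = 0.95,
                         alpha = 0.05, target_power = 0.8, lam = 1,
                         m = 20L, c = 80L, w = 0) {
  stopifnot(is.numeric(delta), length(delta) == 1L,
            is.numeric(sigma_b2), length(sigma_b2) == 1L,
            is.numeric(sigma_w2), length(sigma_w2) == 1L)
  if (sigma_b2 < 0) stop("'sigma_b2' must be non-negative")
  if (sigma_w2 <= 0) stop("'sigma_w2' must be positive")
  if (delta == 0) stop("'delta' must be non-zero")
  if (!(alpha > 0 && alpha < 1)) stop("'alpha' must lie in (0, 1)")
  if (!(target_power > 0 && target_power < 1))
    stop("'target_power' must lie in (0, 1)")
  if (!(lam > 0)) stop("allocation ratio 'lam' must be positive")
  if (!(w >= 0 && w < 1)) stop("attrition 'w' must lie in [0, 1)")
  m <- as.integer(m); c <- as.integer(c)
  if (m < 1L) stop("'m' must be a positive integer")
  if (c < 1L) stop("'c' must be a positive integer")

  out <- list(delta = delta, sigma_b2 = sigma_b2, sigma_w2 = sigma_w2,
              alpha = alpha, target_power = target_power, lam = lam,
              m = m, c = c, w = w,
              sigma2 = sigma_b2 + sigma_w2,
              rho = sigma_b2 / (sigma_b2 + sigma_w2))
  class(out) <- "trial_design"
  out
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Cluster RCT design\n")
  cat(sprintf("  clusters: %d of size %d  (allocation ratio %.3g)\n",
              x$c, x$m, x$lam))
  cat(sprintf("  effect size delta = %.4g;  sigma2 = %.4g (ICC %.4g)\n",
              x$delta, x$sigma2, x$rho))
  cat(sprintf("  alpha = %.3g (two-sided), target power = %.3g, attrition w = %.3g\n",
              x$alpha, x$target_power, x$w))
  invisible(x)
}

#' Numbers of same-arm pair-merges per treatment arm
#'
#' Bookkeeping for homogeneous cluster merges: `k0` pairs of control-arm
#' clusters and `k1` pairs of intervention-arm clusters each combine into a
#' single cluster.  A cluster can take part in at most one merge, so each arm
#' must contain at least `2 * k` clusters.
#'
#' @param k0,k1 Non-negative integers: pair-merges in the control and
#'   intervention arm respectively.
#' @return An object of class `merge_counts`.
#' @examples
#' merge_counts(5, 5)
#' @export
merge_counts <- function(k0 = 0L, k1 = 0L) {
  k0 <- as.integer(k0); k1 <- as.integer(k1)
  if (k0 < 0L || k1 < 0L) stop("merge counts must be non-negative")
  structure(list(k0 = k0, k1 = k1), class = "merge_counts")
}

# split total clusters into (control, intervention) counts per lam = c0/c1
arm_sizes <- function(c, lam) {
  c1 <- round(c / (1 + lam))
  c0 <- c - c1
  if (c1 < 1L || c0 < 1L)
    stop("allocation ratio leaves an empty arm")
  c(c0 = c0, c1 = c1)
}
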