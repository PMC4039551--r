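#' Individually randomised sample size for a difference in means
#'
#' Total number of individuals required for a two-arm, individually
#' randomised trial to detect a difference in means `delta` with two-sided
#' significance level `alpha` and power `target_power`, under the normal
#' approximation, allowing for an anticipated attrition proportion `w`:
#' \deqn{n = \frac{(1+\lambda)^2 (\xi_{\alpha/2} + \xi_\beta)^2 \sigma^2}
#'            {(1-w)\,\lambda\,\delta^2},}
#' where \eqn{\xi_v} is the upper-\eqn{v} standard-normal quantile and
#' \eqn{\lambda} the allocation ratio.  The result is rounded up to the next
#' integer.
#'
#' @param design A [trial_design()].
#' @return Required total sample size (integer).
#' @examples
#' sample_size_individual(trial_design(delta = 0.2, sigma_b2 = 0, sigma_w2 = 1))
#' # 786
#' @export
sample_size_individual <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  xi_a <- stats::qnorm(1 - design$alpha / 2)
  xi_b <- stats::qnorm(design$target_power)
  n <- (1 + design$lam)^2 * (xi_a + xi_b)^2 * design$sigma2 /
    ((1 - design$w) * design$lam * design$delta^2)
  as.integer(ceiling(n))
}

#' Design effect for clustered outcomes, allowing unequal cluster sizes
#'
#' Inflation of the individually randomised sample size caused by
#' intracluster correlation.  With equal clusters of size `m_bar` the classic
#' factor is \eqn{1 + (m - 1)\rho}.  When cluster sizes vary with variance
#' `size_var` about mean `m_bar`, the factor becomes
#' \deqn{1 + \left(\left(\frac{s_c^2}{m_c^2} + 1\right) m_c - 1\right)\rho,}
#' which is strictly increasing in the size variance whenever \eqn{\rho > 0}.
#'
#' @param m_bar Mean cluster size (>= 1).
#' @param rho Intracluster correlation coefficient, in [0, 1).
#' @param size_var Variance of cluster sizes (>= 0); 0 recovers the
#'   equal-size design effect.
#' @return The design effect (scalar >= 1).
#' @examples
#' design_effect(20, 0.05)            # 1.95
#' design_effect(20, 0.05, 90.40)     # about 2.18
#' @export
design_effect <- function(m_bar, rho, size_var = 0) {
  stopifnot(m_bar >= 1, rho >= 0, rho < 1)
  if (size_var < 0) stop("'size_var' must be non-negative")
  1 + ((size_var / m_bar^2 + 1) * m_bar - 1) * rho
}

#' Number of clusters required for a cluster randomised trial
#'
#' Applies the attrition-adjusted design effect
#' \eqn{1 + (m(1-w) - 1)\rho} to the individually randomised sample size and
#' converts to a number of clusters of planned size `m`:
#' \deqn{c = \frac{(1+\lambda)^2 (\xi_{\alpha/2}+\xi_\beta)^2 \sigma^2}
#'            {m (1-w) \lambda \delta^2}\,\{1 + (m(1-w)-1)\rho\}.}
#' The count is rounded up; when `lam = 1` it is rounded up to the next even
#' number so the arms can be split equally (conservative convention).
#'
#' @param design A [trial_design()].
#' @return Required total number of clusters (integer).
#' @examples
#' clusters_required(trial_design())   # 78 for the 20-per-cluster design
#' @export
clusters_required <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  xi_a <- stats::qnorm(1 - design$alpha / 2)
  xi_b <- stats::qnorm(design$target_power)
  me <- design$m * (1 - design$w)
  c_raw <- (1 + design$lam)^2 * (xi_a + xi_b)^2 * design$sigma2 *
    (1 + (me - 1) * design$rho) / (me * design$lam * design$delta^2)
  cc <- ceiling(c_raw)
  if (design$lam == 1 && cc %% 2 == 1) cc <- cc + 1
  as.integer(cc)
}

#' Mean cluster size after pair-merges
#'
#' When `k` pairs among `c` equal clusters of size `m` each combine into one
#' cluster, `c - k` clusters remain and the average cluster size becomes
#' \eqn{\tilde m = cm / (c - k)}.  The total number of individuals is
#' conserved: \eqn{\tilde m (c - k) = mc}.
#'
#' @param m Cluster size before merging (positive integer).
#' @param c Number of clusters before merging.
#' @param k Number of pair-merges, `0 <= k <= c/2` (each cluster may join at
#'   most one merge).
#' @return Post-merge mean cluster size.
#' @examples
#' merged_mean_size(20, 80, 4)   # 21.05...
#' @export
merged_mean_size <- function(m, c, k) {
  stopifnot(m >= 1, c >= 1)
  if (k < 0 || k > c / 2)
    stop("'k' must satisfy 0 <= k <= c/2: each cluster merges at most once")
  c * m / (c - k)
}

#' Sample variance of cluster sizes after pair-merges
#'
#' After `k` pair-merges among `c` equal clusters of size `m`, the remaining
#' size vector holds `k` clusters of size `2m` and `c - 2k` of size `m`.  Its
#' sample variance (divisor `c - k - 1`) has the closed form
#' \deqn{\tilde s_c^2 = \frac{m^2 k (c - 2k)}{(c-k)(c-k-1)}.}
#' It is 0 at `k = 0` and `k = c/2` (all sizes equal) and attains an interior
#' maximum in between.
#'
#' @inheritParams merged_mean_size
#' @return Post-merge sample variance of cluster sizes.
#' @examples
#' merged_size_variance(20, 80, 2)    # 10.12...: one merge per arm of 40
#' merged_size_variance(20, 80, 40)   # 0: every cluster merged
#' @export
merged_size_variance <- function(m, c, k) {
  stopifnot(m >= 1, c >= 1)
  if (k < 0 || k > c / 2)
    stop("'k' must satisfy 0 <= k <= c/2: each cluster merges at most once")
  if (c - k < 2)
    stop("fewer than two clusters remain: sample variance undefined")
  m^2 * k * (c - 2 * k) / ((c - k) * (c - k - 1))
}

#' Cluster allocation ratio after unequal numbers of merges per arm
#'
#' Starting from `c0` control and `c1` intervention clusters, `k0` and `k1`
#' same-arm pair-merges leave `c0 - k0` and `c1 - k1` clusters, so the
#' allocation ratio becomes \eqn{\tilde\lambda = (c_0 - k_0)/(c_1 - k_1)}.
#' Departures from 1 reduce power.
#'
#' @param c0,c1 Clusters per arm before merging.
#' @param k0,k1 Pair-merges per arm; `2 * k` must not exceed the arm size.
#' @return The post-merge allocation ratio.
#' @examples
#' post_merge_allocation_ratio(40, 40, 3, 0)   # 0.925
#' @export
post_merge_allocation_ratio <- function(c0, c1, k0, k1) {
  if (2 * k0 > c0 || 2 * k1 > c1)
    stop("merge counts exceed available clusters in an arm")
  if (c1 - k1 == 0) stop("no clusters remain in the intervention arm")
  (c0 - k0) / (c1 - k1)
}

# gamma of the normal-approximation power formula:
# power = Phi(sqrt(gamma) - xi_{alpha/2})
power_gamma <- function(m_eff, c, lam, delta, sigma2, deff) {
  m_eff * c * lam * delta^2 / ((1 + lam)^2 * sigma2 * deff)
}

#' Analytic power of a cluster randomised trial, before or after merges
#'
#' Normal-approximation power for the difference in means:
#' \deqn{1 - \beta = \Phi\!\left(\sqrt{\gamma} - \xi_{\alpha/2}\right),\qquad
#'   \gamma = \frac{m(1-w)\, c\, \lambda\, \delta^2}
#'            {(1+\lambda)^2 \sigma^2 \{1 + (m(1-w)-1)\rho\}}.}
#'
#' When pair-merge counts are supplied, the design quantities are updated
#' before evaluating the same formula: the cluster count falls to
#' \eqn{\tilde c = c - k_0 - k_1}, the mean cluster size rises to
#' \eqn{\tilde m = cm/(c-k)}, the design effect uses the variable-size form
#' ([design_effect()]) with the post-merge size variance
#' ([merged_size_variance()]), and the allocation ratio becomes
#' \eqn{\tilde\lambda} ([post_merge_allocation_ratio()]).  Any merge strictly
#' reduces power (\eqn{\tilde\gamma \le \gamma}, equality only at `k = 0`).
#'
#' @param design A [trial_design()].
#' @param merges Optional [merge_counts()] of same-arm pair-merges.
#' @return Achieved power, in (0, 1), unrounded.
#' @examples
#' d <- trial_design()
#' crt_power(d)                        # about 0.817
#' crt_power(d, merge_counts(5, 5))    # lower
#' @export
crt_power <- function(design, merges = NULL) {
  stopifnot(inherits(design, "trial_design"))
  xi_a <- stats::qnorm(1 - design$alpha / 2)
  m_eff <- design$m * (1 - design$w)

  if (is.null(merges)) {
    deff <- 1 + (m_eff - 1) * design$rho
    g <- power_gamma(m_eff, design$c, design$lam, design$delta,
                     design$sigma2, deff)
    return(stats::pnorm(sqrt(g) - xi_a))
  }

  stopifnot(inherits(merges, "merge_counts"))
  arms <- arm_sizes(design$c, design$lam)
  k0 <- merges$k0; k1 <- merges$k1
  if (2 * k0 > arms["c0"] || 2 * k1 > arms["c1"])
    stop("merge counts exceed available clusters in an arm")
  k <- k0 + k1
  c_new <- design$c - k
  m_new <- merged_mean_size(design$m, design$c, k)
  s2_new <- merged_size_variance(design$m, design$c, k)
  lam_new <- post_merge_allocation_ratio(arms["c0"], arms["c1"], k0, k1)
  deff <- design_effect(m_new * (1 - design$w), design$rho,
                        s2_new * (1 - design$w)^2)
  g <- power_gamma(m_new * (1 - design$w), c_new, lam_new, design$delta,
                   design$sigma2, deff)
  unname(stats::pnorm(sqrt(g) - xi_a))
}

#' Cluster-size variability as a function of the number of merges
#'
#' Evaluates [merged_size_variance()] over `k = 0, ..., c/2` for one or more
#' starting cluster counts, giving the characteristic rise-and-fall curve of
#' post-merge size variability.
#'
#' @param m Cluster size before merging.
#' @param c Vector of starting cluster counts.
#' @return A data frame with columns `c`, `k`, `size_variance`.
#' @examples
#' head(size_variance_curve(20, c(10, 20, 40, 80)))
#' @export
size_variance_curve <- function(m = 20L, c = c(10L, 20L, 40L, 80L)) {
  out <- lapply(c, function(cc) {
    k <- 0:(cc %/% 2)
    data.frame(c = cc, k = k,
               size_variance = vapply(k, function(kk)
                 merged_size_variance(m, cc, kk), numeric(1)))
  })
  do.call(rbind, out)
}

#' Analytic power surface over a grid of per-arm merge counts
#'
#' @param design A [trial_design()].
#' @param k0_max,k1_max Largest per-arm merge counts to evaluate.
#' @return A data frame with columns `k0`, `k1`, `power`.
#' @examples
#' power_surface(trial_design(), 3, 2)
#' @export
power_surface <- function(design, k0_max, k1_max) {
  grid <- expand.grid(k0 = 0:k0_max, k1 = 0:k1_max)
  grid$power <- mapply(function(a, b)
    crt_power(design, merge_counts(a, b)), grid$k0, grid$k1)
  grid
}
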