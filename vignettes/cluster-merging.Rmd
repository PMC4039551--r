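---
title: "Cluster merging in cluster randomised trials: methods and design choices"
author: "crtmerge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster merging in cluster randomised trials: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtmerge)
```

## The problem

Cluster randomised trials randomise intact groups — general practices,
schools, wards — and pay for it with a design effect: with ICC $\rho$ and
$m$ individuals per cluster, the individually randomised sample size is
inflated by $1 + (m-1)\rho$.  Organisational change can then rewrite the
design mid-trial: two clusters merge, and suddenly cluster sizes are
unequal, there are fewer clusters, and — if the merged pair straddles the
arms — exposure is mixed.  `crtmerge` quantifies both halves of the
problem: the closed-form impact on power at the design stage, and the
behaviour of practical analysis strategies via simulation.

## The design mathematics

All design calculations use the normal approximation: power is
$\Phi(\sqrt{\gamma} - \xi_{\alpha/2})$ with

$$\gamma = \frac{m(1-w)\,c\,\lambda\,\delta^2}
  {(1+\lambda)^2\,\sigma^2\,\{1 + (m(1-w)-1)\rho\}},$$

where $\delta$ is the difference in means, $\sigma^2 = \sigma_b^2 +
\sigma_w^2$ the total outcome variance, $c$ the number of clusters,
$\lambda$ the cluster allocation ratio and $w$ the anticipated
individual-level attrition.  We deliberately use standard-normal quantiles
throughout, with no $t$/Satterthwaite small-sample correction: it keeps the
closed forms exact inverses of each other and matches the Wald $z$ test the
simulation analysis uses.  With 40 clusters per arm the difference is
negligible; with very few clusters both halves of the package would be
mildly anticonservative, and that caveat travels with them.

After $k$ pair-merges among $c$ equal clusters of size $m$, the surviving
$c-k$ clusters have mean size $\tilde m = cm/(c-k)$ and sample size
variance

$$\tilde s_c^2 = \frac{m^2 k (c-2k)}{(c-k)(c-k-1)},$$

which is the textbook sample variance (divisor $c-k-1$) of the explicit
size vector of $k$ doubles and $c-2k$ untouched clusters — the test suite
checks the identity by brute force over a full small-parameter grid.  The
curve rises from 0, peaks, and returns to 0 at $k = c/2$ when all clusters
have paired up and sizes are equal again:

```{r fig-sizevar, fig.width = 6, fig.height = 4}
curve_df <- size_variance_curve(m = 20, c = c(10, 20, 40, 80))
plot(NULL, xlim = c(0, 40), ylim = c(0, max(curve_df$size_variance)),
     xlab = "pair-merges k", ylab = "post-merge size variance")
for (cc in unique(curve_df$c))
  lines(curve_df$k[curve_df$c == cc],
        curve_df$size_variance[curve_df$c == cc], type = "b", pch = 16,
        cex = 0.5, col = which(unique(curve_df$c) == cc))
legend("topright", legend = paste("c =", unique(curve_df$c)),
       col = 1:4, lty = 1, bty = "n")
```

`crt_power()` composes the pieces for a post-merge power: the reduced count
$\tilde c$, the variable-size design effect
$1 + ((\tilde s_c^2/\tilde m^2 + 1)\tilde m - 1)\rho$, and the perturbed
allocation ratio $\tilde\lambda = (c_0 - k_0)/(c_1 - k_1)$.  The source
formulas treat these ingredients one at a time; composing them into a
single operation is this package's contract, with each ingredient also
exported.  Two analytic facts become property tests: $\tilde\gamma \le
\gamma$ with equality only at $k = 0$ (merging never helps), and
$\gamma(\lambda)$ is maximised at $\lambda = 1$ (imbalance never helps).

Sample sizes round up; when $\lambda = 1$ the cluster count rounds up to
the next even number so the arms split equally.  No rounding convention is
universal here; ceiling is the conservative choice.

## What the simulator generates — and what it does not

`generate_trial()` draws from exactly the two-level model above: equal
cluster sizes, equal allocation, one Gaussian cluster effect, Gaussian
individual error, and a cluster-level treatment mean ($\mu_0 = 0$,
$\mu_1 = \delta = 0.2$ by default, $\sigma^2 = 1$, $\rho = 0.05$, $c = 80$,
$m = 20$ — a typical primary-care configuration with 80% planned power).
It does **not** emulate baseline cluster-size variation, covariates,
non-Gaussian outcomes, informative attrition, or more-than-pairwise
merges.  Passing tests therefore demonstrate the behaviour of the analysis
strategies under the idealised mechanism, not robustness of any real trial
to messier departures.

Merge scenarios:

* **S1** (homogeneous, full completion): $k_0$/$k_1$ same-arm pairs are
  drawn uniformly among never-merged clusters per arm and relabelled; no
  outcome changes.  Any test of S1 can therefore assert bit-identical
  outcomes.
* **S2** (homogeneous, partial completion): completers keep their
  pre-merge outcome; the rest of the merged cluster is regenerated with
  **one** new shared cluster-level error.
* **S3** (heterogeneous, full completion): each merge pairs one control
  with one intervention cluster; outcomes untouched, so the merged cluster
  mixes exposures and its expected mean is $(\mu_0+\mu_1)/2$.
* **S4** (heterogeneous, partial completion): non-completers are
  regenerated with the treatment mean implied by the merged cluster's
  post-merge arm, plus a new shared cluster-level error.

Three choices in this machinery were genuinely open:

* *Completer selection.* "Half the individuals" does not say which half;
  we take the first $\lfloor f \cdot m \rfloor$ subjects by within-cluster
  index.  By exchangeability of the generated subjects this is
  distributionally identical to random selection and is reproducible.
* *S4 error convention.* The homogeneous partial scenario explicitly gives
  regenerated non-completers a new cluster-level error; the heterogeneous
  text is silent.  We mirror the homogeneous convention (`"new_shared"`),
  and `merge_spec(noncompleter_cluster_error = "retain_parent")` exposes
  the alternative in which non-completers keep their parent cluster's
  effect and only the mean and individual error are refreshed.
* *Regeneration under exclusion strategies.* Under S4 with `drop_merged` or
  `completers_only` the regenerated records never reach the fitter, so
  their mean is immaterial; we use the pre-merge arm mean so that the
  random-number stream — and hence every shared record — is identical
  across strategies run from the same seed, mirroring the original
  study's design of re-analysing one set of simulated trials several ways.

Analysis strategies (`build_analysis_set()`): `as_one_cluster` (the
pragmatic choice after homogeneous merges), `assign_control`,
`assign_intervention`, `drop_merged`, and `completers_only` (completers
keep their *original* cluster and arm labels).  `as_one_cluster` after a
heterogeneous merge is refused rather than silently mislabelled.

## The model fit

The analysis model is the random-intercept model fitted by REML, with a
two-sided Wald $z$ test for the treatment effect (strict inequality at the
threshold).  Because the harness needs tens of thousands of fits, the
fitter profiles the restricted likelihood over the variance ratio
$\theta = \sigma_b^2/\sigma_w^2$: for cluster-constant covariates the GLS
estimates are weighted arm means of cluster means with weights
$n_j/(1+n_j\theta)$, and the profiled criterion is one-dimensional and
smooth.  It is optimised on $[0, \infty)$ with tolerance $10^{-8}$;
$\hat\sigma_b^2$ is floored at the boundary 0 (then $\widehat{ICC} = 0$).
Non-convergence (never observed in the reported runs) is flagged, and the
harness drops and counts such replicates rather than failing silently.

Correctness is established two ways in the test suite: on balanced layouts
the estimates must equal the one-way ANOVA closed forms
($\hat\sigma_w^2 = MSW$, $\hat\sigma_b^2 = (MSB - MSW)/m$ truncated at 0),
and on unbalanced post-merge data they must match `lme4::lmer` REML fits —
both hold to better than $10^{-6}$.

## Monte Carlo design

`run_cell()` runs one (scenario, strategy, merge-count) combination;
`run_table()` sweeps the merge grid $M = \{0, 1, 2, 5, 10, 20\}$ per arm
(diagonal for tables, full $M \times M$ for response surfaces).  Replicate
$r$ of a cell seeds the RNG with `substream_seed(master, r)`, so any
replicate is reproducible in isolation, and cells sharing a master seed
analyse identical trials under different strategies.  Summaries report
Monte Carlo means with normal 95% intervals (mean $\pm 1.96\,SE$),
empirical power as the rejection fraction, and the mean post-merge
cluster-size variance, which must (and does) agree with the closed form
$\tilde s_c^2$ — the bridge between the analytic and simulated halves.

The default cell size is 1000 replicates, matching the original study; the
reproduction tests run the six-cell homogeneous table at 300 replicates
per cell, widening each printed-precision band by twice the run's own
Monte Carlo standard error so the check stays sharp without re-running the
full study inside the suite.  The remaining single-cell checks use the
full 1000 replicates.  At 1000 replicates an empirical power near 80% has
a Monte Carlo SE of about 1.3 percentage points; differences smaller than
that are noise, which matters when comparing against published cells that
carry the same noise themselves.

## Known limitations

* Normal-approximation design formulas and Wald $z$ inference: slightly
  anticonservative for small numbers of clusters.
* Binary outcomes, baseline size variation, stratified or matched designs,
  arm-differential attrition, merges of more than two clusters, cluster
  fragmentation and membership churn are out of scope.
* The variable-size design effect assumes equal allocation when combined
  with $\tilde\lambda \ne 1$; the composition is a good approximation for
  the mild imbalances merges create, not an exact result.
* The ICC attenuation under merging reflects clusters whose *natural* size
  grows; if analysed clusters were subsamples of larger natural clusters
  the ICC would not change and the full analytic power loss would apply.
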