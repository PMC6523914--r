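---
title: "Detecting differentially methylated regions with kernel distance and scan statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially methylated regions with kernel distance and scan statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrscan)
```

## The data and the testing problem

Bisulfite sequencing reports, for sample $i$ of group $k$ at CpG site
$j$, a methylated read count $m_{kij}$ out of coverage $c_{kij}$, modelled
as $m_{kij} \mid c_{kij} \sim \mathrm{Binomial}(c_{kij}, p_{kij})$. A
differentially methylated region (DMR) is a run of nearby CpG sites whose
methylation rates differ systematically between groups (e.g. cases vs
controls). Two features make this harder than site-by-site testing:
methylation rates at nearby sites are correlated, with correlation
decaying in genomic distance, and coverage varies strongly across sites
and samples, so samples with deep coverage would otherwise dominate.

`dmrscan` implements two region-level tests that address both features,
sharing one covariate-adjustment front end and one permutation inference
back end.

## Covariate adjustment

Methylation is strongly associated with covariates such as age, sex or
batch. Both tests therefore first fit a single binomial logistic
regression of $m_{kij}$ out of $c_{kij}$ on sample-level covariates
$x_{ki}$, pooling all samples from **both** groups and all sites:

$$\log\frac{p_{kij}}{1-p_{kij}} = \beta_0 + \beta_1' x_{ki}.$$

The group label is deliberately excluded — the group effect is exactly
what the downstream tests measure, and pooling keeps the fitted rates
label-free so that they remain valid under label permutation. Fitted
rates $\hat p_{kij}$ depend only on covariates (not on the site), and the
*adjusted methylation count* of a cell is the residual
$r_{kij} = m_{kij} - \hat p_{kij} c_{kij}$. With an intercept present the
logistic score equation forces $\sum_{kij} r_{kij} = 0$, a conservation
property the test suite checks. With no covariates the fit has closed
form: $\hat p$ is the pooled rate $\sum m / \sum c$ everywhere, and the
whole stage reduces to subtracting one constant rate.

For the scan statistic the adjustment additionally acknowledges that the
sites of one subject form a cluster: `mixed_model_adjust()` solves
marginal (population-averaged) estimating equations with an exchangeable
(compound-symmetry) working correlation across a subject's sites and
reports a robust sandwich covariance for the coefficients. Exchangeability
is certainly not the true correlation structure of methylation — the true
structure decays with distance — but the sandwich variance is valid under
misspecification, which is the usual trade of flexibility for robustness.
Because covariates are sample-level, the marginal fitted rates coincide
with the pooled logistic fit when no covariates are present; in that case
the closed form is used directly and only the exchangeable correlation
$\hat\alpha$ is estimated (moment estimator on Pearson residuals). If the
iteration fails, the fit falls back to the pooled logistic fit with a
warning, never silently.

## The kernel distance test (KDM)

Per site, group sums $r_{kj} = \sum_i r_{kij}$ and
$C_{kj} = \sum_i c_{kij}$ give group effects
$\hat\beta_{kj} = r_{kj}/C_{kj}$ and differences
$\delta_j = \hat\beta_{Aj} - \hat\beta_{Uj}$ (with no covariates,
$\delta_j$ is exactly the difference of raw group methylation rates — the
pooled rate cancels). The statistic is the quadratic form

$$Q(\tau) = \delta' A(\tau) \delta, \qquad
A_{jl}(\tau) = \bigl(1 - (d_{jl}/\tau)^2\bigr)^3 \;\text{ if } d_{jl} \le \tau,
\text{ else } 0,$$

a tri-weight kernel in the inter-site distance $d_{jl}$ with bandwidth
$\tau$. The kernel encodes the biology: site pairs further apart than
$\tau$ contribute nothing, and the weight decays smoothly inside. Since
DMR lengths are unknown, $Q$ is maximized over a bandwidth grid; the
default grid has 10 values linearly spaced from the smallest adjacent
inter-site distance to half the span of the region (the standard advice
for cluster-detection bandwidth scans), and a single fixed $\tau$ is
supported for studies with a known target length. Distances can be in bp
(default for real data) or site-index units (natural for equally spaced
simulated sites). Ties in the bandwidth argmax go to the smallest
$\tau$.

When $Q(\tau^*) \ne 0$, the per-site contributions
$U_j(\tau^*)/Q(\tau^*)$ with
$U_j = \sum_l A_{jl}\delta_j\delta_l$ sum to one and act as a smoother:
peaks localize the DMR. `call_dmrs()` reports the contiguous run of sites
around the peak whose contribution exceeds a configurable quantile
(default 0.95) of the per-site contributions — a pragmatic rule, since
peak-to-boundary conversion admits no canonical definition.

A scaled chi-square approximation exists for a single fixed bandwidth,
but not for the maximum over a grid; inference is therefore purely
permutation-based (below).

## The binomial scan statistic (SSM)

The scan statistic treats the group-level adjusted counts of a window as
binomial. Three preparation steps make that tenable:

1. **Recentring.** Residual counts are zero-centred by construction, so
   they cannot be binomial. The group counts are recentred by adding back
   the grand-mean fitted count:
   $R_{kj} = \sum_i \bigl(m_{kij} - (\hat p_{kij} - \bar p) c_{kij}\bigr)$
   with $\bar p$ the coverage-weighted mean fitted rate, clamped to
   $[0, C_{kj}]$. With no covariates this recovers the raw group counts
   exactly, so the calibration studies are unaffected by the convention;
   with covariates it removes covariate-driven rate differences while
   keeping counts on the binomial scale.
2. **Design effect.** Reads within one sample at one site are not
   independent Bernoulli draws. The classical variance-inflation
   correction for clustered binary data divides group counts and
   coverages by $\mathrm{deff}_{kj} = 1 + (\bar c_{kj} - 1)\hat\rho_j$,
   where $\bar c_{kj}$ is the group's mean coverage at site $j$ and
   $\hat\rho_j$ the one-way ANOVA moment estimate of the intra-site
   correlation, computed across **all** samples so it is label-free.
   The design effect is floored at 1 (it can only shrink the effective
   number of reads) and degrades to a no-op when $\hat\rho = 0$ or
   coverage is 1.
3. **Pseudo-counts.** One pseudo-read each is added to the methylated and
   unmethylated counts of every group at every site
   ($\tilde r \to \tilde r + 1$, $\tilde C \to \tilde C + 2$), pulling
   proportions off the 0/1 boundary so the likelihood ratio is always
   defined; the implicit prior content of the added reads is the null.

For a window $W$ of $w$ consecutive sites, with per-group window sums
$(r_k, C_k)$, the statistic is the binomial log-likelihood ratio

$$\mathrm{LR}_W = \sum_k \Bigl[r_k \log \hat p_k + (C_k - r_k)\log(1-\hat p_k)\Bigr]
 - \Bigl[r \log \hat p + (C - r)\log(1-\hat p)\Bigr],$$

with per-group MLEs $\hat p_k = r_k/C_k$ and the pooled
$\hat p = r/C$. For two groups $2\,\mathrm{LR}$ is the familiar
$G^2$ deviance of the 2×2 table; for $G > 2$ nominal groups the same
expression is the multinomial generalization and reduces exactly to the
binomial case at $G = 2$. Ordered group alternatives are not supported:
the order-constrained MLEs have no closed form, and the unordered
statistic would not honor the ordering. Counts stay real-valued after the
design-effect division; the LR is evaluated on real counts without
rounding.

The scan slides windows of every requested size (default
$\{5, 10, 15, 20, 25, 30\}$ sites, step 1) across the region; the global
statistic is the maximum over all windows and sizes, which removes the
bandwidth-selection problem the kernel test faces. Per-window p-values
are computed against the permutation distribution of the **global
maximum**, so they control family-wise error across the many overlapping
windows (a step-down refinement would be less conservative but is not
implemented). `call_dmrs()` then selects windows with
$p \le \alpha$ greedily by descending LR, discarding overlaps — a simple
rule chosen because any maximal non-overlapping selection needs a
tie-break and LR order is the natural one.

## Permutation inference

Both tests permute subject group labels. Because the adjustment model
excludes the group, the adjusted counts (and the intra-site correlations
$\hat\rho_j$) are computed once and stay fixed; each permutation only
re-forms group sums, which reduces to two matrix products per test and
makes $B$ in the thousands cheap. The p-value is the add-one estimator
$(1 + \#\{T_\mathrm{perm} \ge T_\mathrm{obs}\})/(B+1)$, counting ties as
exceedances; it is guaranteed in $(0, 1]$ and valid (the achieved level
of the $p \le \alpha$ rule is $\lfloor (B+1)\alpha \rfloor/(B+1)$, just
below nominal). Group-level design effects *are* recomputed per
permutation, since mean group coverage depends on the labelling.

Degenerate situations are handled explicitly rather than silently:
sites where any group has zero total coverage are excluded (both
$\hat\beta_{kj}$ and the LR are undefined there) with a message; a
permuted group with no coverage at a site contributes $\delta_j = 0$;
window sizes exceeding the region are skipped with a warning; one-sample
groups get $\mathrm{deff} = 1$ with a warning.

## The synthetic-data generator

`simulate_dataset()` reproduces a two-group methylation study with a
single embedded DMR:

- $N_1$ cases and $N_2$ controls at $m$ equally spaced CpG sites, with
  $r$ consecutive sites centered in the region forming the DMR (ties in
  centering resolved toward the lower index). Defaults:
  $N_1 = N_2 = 24$, $m = 24$, $r = 6$.
- Latent per-site methylation levels $X$ drawn from
  $\mathrm{Beta}(\alpha_U, \beta_U)$ — defaults $(0.1, 0.9)$ — except for
  cases inside the DMR, which use $(\alpha_A, \beta_A)$. The effect size
  is the difference of Beta means
  $d = \alpha_A/(\alpha_A+\beta_A) - \alpha_U/(\alpha_U+\beta_U)$;
  $\alpha_A = \alpha_U$, $\beta_A = \beta_U$ gives the null.
- Cross-site dependence through a Gaussian copula whose correlation
  matrix has unit diagonal and off-diagonal $\rho/|i-j|$ — adjacent
  sites correlate at $\rho$ (default 0.5), decaying inversely with
  distance. The matrix must be positive definite as given; for this
  family that holds comfortably at the default sizes
  ($\rho \le 0.7$, $m \le 30$) but fails for large $\rho$ at larger
  $m$, in which case the generator refuses with an error rather than
  repairing the matrix.
- Transform to correlated rates:
  $p = 1 - \Phi(C\,\Phi^{-1}(1 - X))$ with $C$ the lower Cholesky factor.
  This normal-score transform is linear in the scores, so the rates'
  normal scores inherit the $\rho/|i-j|$ correlation exactly — but since
  $\Phi^{-1}(1-X)$ is not standard normal for Beta $X$, the transform
  **distorts the Beta marginals** (it compresses rates toward 0 for the
  default parameters). This verbatim transform is nevertheless the
  default, because it is the generator under which the package's
  calibration targets are defined; `proper_copula = TRUE` inserts the
  Beta CDF first ($X \to F_\mathrm{Beta}(X)$), which preserves marginals
  exactly and is the better choice for new power studies. Beta draws are
  clamped to $[10^{-300}, 1-10^{-16}]$ before the normal quantile to
  avoid infinities from underflowing draws.
- Coverage $\;c = \max(c_\mathrm{min}, \mathrm{round}\,N(\mu_c, \sigma_c))$
  with defaults $\mu_c = 30$, $\sigma_c = 13$ (read as a standard
  deviation; a variance of 13 would make coverage nearly constant, which
  contradicts the clamp being specified at all), $c_\mathrm{min} = 5$ —
  typical of reduced-representation bisulfite sequencing depth. Counts
  are then $\mathrm{Binomial}(c, p)$.

What the generator does **not** emulate: covariate effects (covariate
handling is exercised by unit tests instead), irregular site spacing,
multiple DMRs per region, site-specific dispersion beyond the binomial,
and missingness/zero coverage. Passing calibration on this generator
therefore shows correct type-I error under distance-decaying
exchangeable-ish dependence with varying coverage — not robustness to
every feature of real bisulfite data.

## Calibration and power studies

`benchmark_type1()` runs the full pipeline (simulate, adjust, test) on
independent null datasets and reports rejection fractions with binomial
Monte-Carlo standard errors; it refuses configurations with $d \ne 0$ so
a rejection rate is never misread as a type-I error. `benchmark_power()`
does the same across a grid of $\alpha_A$ values; both methods run on the
same datasets, so method contrasts are paired. Reproducibility follows a
counter scheme: the master seed seeds one stream from which a
per-replicate seed triple (dataset, KDM permutations, SSM permutations)
is drawn up front, so results do not depend on which methods are enabled.

Problem sizes: the packaged acceptance script uses 5,000 replicates with
$B = 500$ permutations per dataset for each $\rho \in \{0.5, 0.7\}$
(minutes on one CPU); the test suite's calibration check uses 2,000
replicates with $B = 200$, and its power check 500 replicates at
$\alpha_A \in \{0.3, 0.6\}$ ($d \in \{0.15, 0.3\}$) for total sample
sizes 48 and 60. With the 6-site DMR matched by $\tau = 6$ and a 6-site
window, these studies exercise both tests at their intended operating
point.

## Numerical choices, in one place

- Permutation p-values: add-one estimator, ties count as exceedances.
- Bandwidth ties: smallest $\tau$ wins (`tau_argmax_ties`).
- Kernel evaluated with the scaled-distance condition $d/\tau \le 1$;
  diagonal exactly 1; boundary exactly 0.
- LR evaluated via `log1p` on the complement side for accuracy near 0/1;
  pseudo-counts guarantee the arguments stay interior.
- Design effect floored at 1; intra-site ICC set to 0 where the ANOVA
  moment estimator is undefined (no variation, or a single contributing
  sample).
- GEE iteration: damped only by its natural step, convergence tolerance
  `1e-8` on the max coefficient change, exchangeable correlation clipped
  to $[0, 0.99]$.
- Coordinates: 1-based inclusive positions internally (matching bismark
  coverage files); BED export converts to 0-based half-open; the results
  TSV carries statistics at full `%.17g` precision so round-trips are
  bit-exact.

## Known limitations

- KDM is limited to two groups; SSM handles any number of nominal groups
  but no ordered alternatives.
- Per-window p-values inherit the conservatism of the global-max null;
  closely spaced distinct DMRs can shadow each other in the greedy
  calling step.
- The exchangeable working correlation is a deliberate simplification;
  its role is efficiency, not validity (inference is by permutation).
- No FDR control across regions or chromosomes is attempted: each region
  analysis is self-contained, and multiplicity across regions is the
  caller's responsibility.
- The verbatim copula default means simulated marginal rates are *not*
  Beta$(\alpha, \beta)$; interpret effect sizes on the latent scale, or
  switch to `proper_copula = TRUE`.
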