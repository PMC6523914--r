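# dmrscan

Region-level tests for **differentially methylated regions (DMRs)** from
bisulfite-sequencing count data, for statistical geneticists and
epigenomics analysts working with bismark-style per-CpG methylation
counts.

Bisulfite sequencing yields, for each sample and CpG site, a methylated
read count `m` out of a coverage `c`, with `m | c ~ Binomial(c, p)`.
Methylation rates at nearby CpG sites are correlated, with correlation
decaying in genomic distance, so single-site tests waste power and
region-level tests must model that dependence. `dmrscan` implements two
complementary region tests that do:

**Kernel distance test (KDM).** After covariate adjustment, the per-site
case–control differences `δ_j = β̂_Aj − β̂_Uj` of adjusted methylation
rates are combined in the quadratic form

    Q(τ) = δ' A(τ) δ,    A_jl(τ) = (1 − (d_jl/τ)²)³ for d_jl/τ ≤ 1, else 0

with a compact-support **tri-weight kernel** that down-weights site pairs
by distance `d_jl` and a bandwidth `τ`. The observed statistic is
`max_τ Q(τ)` over a bandwidth grid; per-site contributions
`U_j(τ*)/Q(τ*)` localize the signal.

**Binomial scan statistic (SSM).** Counts are covariate-adjusted with a
marginal logistic fit using an exchangeable within-subject correlation,
corrected for read clustering within CpG sites by a design effect
`deff = 1 + (c̄ − 1)ρ̂`, and stabilized with +1 pseudo-counts. For every
window `W` of `w` consecutive sites, the binomial log-likelihood ratio

    LR_W = ℓ(p̂_A, p̂_U) − ℓ(p̂_pooled)

compares separate group methylation rates against a shared one; the
global statistic is `LR = max_w max_W LR_W` over moving windows of
variable size. The statistic generalizes to more than two (unordered)
groups via the multinomial likelihood.

Both tests get p-values by permuting subject group labels (add-one
estimator, `(1 + #{stat_perm ≥ stat_obs})/(B + 1)`); the adjustment
model excludes the group label, so adjusted counts stay fixed under
permutation. A Gaussian-copula beta-binomial simulator with
`ρ/distance` inter-site correlation generates synthetic datasets for
calibration and power studies.

## Worked example

Simulate a 48-sample study (24 cases, 24 controls, 24 CpG sites with a
6-site DMR in the middle, effect size d = 0.3) and test it with both
methods:

```r
library(dmrscan)

cfg  <- simulation_config(alpha_A = 0.6, rho = 0.5, seed = 42)  # d = 0.3
data <- simulate_dataset(cfg)
data
#> methylation_dataset: 48 samples x 24 CpG sites
#>   groups: A=24, U=24
#>   coverage: median 30 range 5 - 69

kdm_test(data, tau = 6, distance_unit = "index", permutations = 999, seed = 1)
#> Kernel distance test (24 sites)
#>   Q* = 0.236459 at tau* = 6 (index units)
#>   permutation p-value = 0.002 (B = 999)

ssm <- ssm_scan(data, window_sizes = 6, permutations = 999, seed = 2)
ssm
#> Binomial scan statistic (2 groups, 19 windows)
#>   global LR = 16.1583, permutation p-value = 0.001 (B = 999)
#>   DMR calls at alpha = 0.05 : 1
ssm$calls
#>   chromosome start_bp end_bp n_sites statistic p_value method
#> 1       sim1       11     16       6  16.15835   0.001    SSM
```

Both tests reject decisively, and the scan's best window (sites 11–16)
covers the true DMR (sites 10–15). `Q*` is the kernel quadratic form at
the selected bandwidth; the `LR` is the window log-likelihood ratio, and
both p-values are permutation-based, so their resolution is `1/(B+1)`.

Real data enter through `read_coverage_files()` (bismark coverage TSVs +
a sample sheet); calls are exported with `write_dmr_bed()` (BED6 plus a
full-precision TSV). A command-line wrapper lives at
`inst/scripts/dmrscan`:

```sh
Rscript inst/scripts/dmrscan simulate --out sim --seed 3
Rscript inst/scripts/dmrscan ssm --sample-sheet sim_samples.tsv \
    --out res --window-sizes 5,10,15 --permutations 1000 --seed 1
```

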