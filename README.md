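# phylogee

Phylogenetically corrected association between gene presence/absence and
an environmental gradient, plus a metagenomic gene-frequency estimator —
for comparative microbiologists asking questions like *"is this gene
retained preferentially by lineages from iron-poor habitats?"* without
being fooled by shared ancestry.

Species are not independent data points: close relatives inherit both
their gene content and their habitat, so ordinary logistic regression
across a clade drastically overstates significance.  `phylogee` fits
binomial **generalized estimating equations (GEE)** whose working
correlation comes from the phylogeny, and refers Wald tests to a reduced,
*phylogenetic* degrees of freedom.

## The model

For tips `i = 1..n` with gene indicator `y_i` and ordinal environment
`x_i` (iron: 0 = scarce/open ocean, 1 = medium/coastal, 2 =
high/freshwater), the mean is `mu_i = logit^-1(b0 + b1 x_i)` and `b`
solves

    U(b) = D' V^-1 (y - mu) = 0,    V = phi A^1/2 R A^1/2

where `A = diag(mu(1-mu))`, `D = A X`, and `R` is the phylogenetic
correlation: `V_ij` = branch length shared by tips `i` and `j` from the
root (Brownian covariance), standardized to unit diagonal.  Wald p-values
use a t distribution with `dfP - p` degrees of freedom, where

    dfP = n * (total branch length) / (sum of root-to-tip distances)

is the phylogenetic degrees of freedom (star tree: `dfP = n`; correlated
clades: much less).  Model-based and observation-level sandwich standard
errors are both reported.

Around the fit, the package provides the full pipeline: presence calling
from 12-column tabular homology hits with a complete-genome rule for
calling absence, greedy identity-threshold clustering, removal of
near-duplicate tips (< 0.5% rRNA divergence with identical state and
environment), per-habitat presence tallies, a single-copy-core-gene
normalized metagenomic gene-frequency estimator with Spearman
correlations (exact permutation p below n = 10), and a fully seeded
simulator (birth-death trees; joint environment x trait continuous-time
Markov chain; Poisson per-site hit counts) so everything is testable
without downloads.

## Worked example

Simulate a 64-tip clade in which the gene's loss rate rises with iron
(stationary slope −2 on the logit scale), with the environment itself
evolving on the tree, then fit the phylogenetic GEE:

```r
library(phylogee)
cfg <- sim_config(seed = 3, n_tips = 64, trait_rate_scale = 1,
                  env_rates = default_env_rates(2))
ds  <- simulate_dataset(cfg)
fit <- fit_gee(gee_design(ds$tree, ds$traits))
print(fit)
#> Phylogenetic GEE fit (binomial family, working correlation)
#>             estimate se_naive se_robust      p
#> (Intercept)   1.3718   0.8344    0.9579 0.1197
#> iron_level   -0.9075   0.1768    0.4442 0.0001
#> phi = 0.8909   dfP = 17.97   iterations = 2
```

The fitted iron coefficient is negative (−0.91): each step up in iron
availability multiplies the odds of carrying the gene by about `exp(-0.91)
= 0.40`.  Although the tree has 64 tips, the test is referred to `dfP - 2
= 16` degrees of freedom — the effective information in the clade — and
still rejects no-association at `p = 1e-4`:

```r
wald_report(fit, "iron_level")
#> $statistic  -5.13
#> $df         16
#> $p          0.000101
```

The same dataset carries a simulated 40-site metagenome panel; the
core-gene-normalized frequency of the target declines with predicted
iron:

```r
site_correlation(gene_frequency(ds$sites))
#>   taxon        rho            p n_sites n_excluded
#> 1   sim -0.8320511 2.874211e-11      40          0
```

`rho = -0.83`: sites with more available iron carry proportionally fewer
gene copies per genome.

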