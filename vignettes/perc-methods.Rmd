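---
title: "Gene-grouped penalized regression for rare and common variants"
author: "PeRC package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-grouped penalized regression for rare and common variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PeRC)
```

## The problem

Single-marker association tests are underpowered for rare variants: a SNP
carried by a handful of individuals cannot, on its own, produce a
detectable signal. Burden methods answer this by collapsing the rare
variants of a gene into one count, but they usually discard the common
variants and test one gene at a time, ignoring everything outside the
gene under test. PeRC (penalized regression of rare and common variants)
instead fits **all genes simultaneously** in one sparse regression: each
gene contributes its common variants plus a single collapsed rare-variant
burden column, a group penalty selects or discards whole genes, and
within-gene penalties keep the model sparse at the variant level. Common
SNPs outside any gene enter as their own singleton groups, so
intergenic signals are not silently lost.

## The model

For a quantitative trait $y_i$ on $m$ individuals the linear predictor is

$$\eta_i = \beta_0 + \sum_{g=1}^{G}\Big(\sum_{c\in g_c} x_{ic}\beta_c
  + \gamma_g \, z_{ig}\Big), \qquad
z_{ig} = 2\,\frac{b_{ig}-d_{min}}{d_{max}-d_{min}},\quad
b_{ig}=\sum_{r \in g_r} x_{ir},$$

where $g_c$ and $g_r$ are the common (MAF $\ge \tau$) and rare
(MAF $< \tau$) variants of group $g$, and $z_{ig}$ rescales the raw
rare-allele burden $b_{ig}$ to the dosage range $[0,2]$ using the
smallest and largest burden observed in the sample. The fit maximizes
the penalized negative residual sum of squares

$$O = -\tfrac12\sum_i (y_i-\eta_i)^2 - f(\beta), \qquad
f = \sum_g \Big[\lambda_1 s_g\big(\textstyle\sum_{c\in g_c}\beta_c^2 +
\gamma_g^2\big)^{1/2} + \lambda_2\big(\textstyle\sum_{c\in g_c}
\omega_c|\beta_c| + r_g|\gamma_g|\big) + \lambda_3\big(\textstyle
\sum_{c\in g_c}\omega_c\beta_c^2 + r_g\gamma_g^2\big)\Big].$$

The three terms are a group lasso over genes, a weighted lasso within
genes, and a weighted ridge; $\lambda_1=0$ recovers a weighted elastic
net, and with every SNP treated as rare ($\tau = 1$) and $\lambda_3=0$
the objective is a sparse group lasso over the collapsed columns. By
default the strengths are tied to one sparsity dial,
$(\lambda_1,\lambda_2,\lambda_3) = \kappa(1,1,1)$: large $\kappa$ gives
the empty model, and `kappaMax()` returns the smallest such $\kappa$
from the subgradient condition at zero
($|x_j^\top(y-\bar y)| \le \kappa(s_{g(j)}+w_j)$ for every column).

Weights put the penalty on a comparable scale across predictors without
standardizing the design: $\omega_c = 2\sqrt{\mathrm{MAF}_c
(1-\mathrm{MAF}_c)}$ per common variant (twice the allele-indicator
standard deviation, as used in the Mendel software's GWAS lasso),
$r_g = \sqrt{f_r(1-f_r)}$ on the collapsed column, and
$s_g = \sqrt{l_g/\max_g l_g}$ per group, where $l_g$ counts the group's
common variants plus one if it has a collapsed column. The group scale
prevents large genes from being preferred merely for their extra degrees
of freedom; the maximal group always has $s_g = 1$.

Two definitional points were genuinely open and are resolved as follows.
*The collapsed-locus frequency* $f_r$ is taken as the pooled minor
allele frequency of the group's rare SNPs,
$f_r = \min(f, 1-f)$ with $f = \sum_i b_{ig} / (2 m |g_r|)$ — the
natural "allele frequency" of a synthetic locus formed by pooling rare
alleles; carrier frequency and column-mean conventions were considered
and rejected because they are not frequencies of alleles. *Groups with
no common variants and no burden variation* contribute nothing and are
dropped; a constant-burden collapsed column (no individual differs)
cannot be rescaled and is dropped with a warning rather than imputed.

## Optimization

The objective is maximized by cyclic coordinate ascent with safeguarded
Newton (CLG) updates, implemented in C++. Each coordinate takes the step
$-O'/O''$ built from one-sided derivatives where the penalty has kinks:
at $\beta_j = 0$ both directions are examined and a move is made only if
it improves the objective, which keeps exact zeros exact (no smoothing
constant is ever added). A proposed move that fails to improve the
objective is halved and reattempted, up to `maxHalvings` (default 30)
times; a move may not cross zero in one step — it is clamped at zero and
may continue from there on the next cycle. The intercept is unpenalized
and updated first in every cycle; columns follow in fixed design order,
so runs are exactly reproducible. Convergence is declared when the
relative objective change over a full cycle falls below `tol` (default
`1e-8`, at most 1000 cycles); these are conventional engineering values,
and the defaults can be tightened through `percControl()` when
coefficient-level accuracy matters (the package's own OLS-limit checks
use `tol = 1e-15`). Because every accepted update strictly improves the
objective, the objective trace is non-decreasing by construction — the
test suite asserts this on per-update traces. When the curvature
vanishes (possible only with $\lambda_3 = 0$ at a degenerate point) the
step falls back to magnitude 1 before halving.

`percFitPath()` fits a descending $\kappa$ grid with warm starts
(default: 20 log-spaced values from $\kappa_{max}$ to
$0.01\,\kappa_{max}$; no grid is prescribed by the method itself).
Model size along the path is monotone in practice but not by theorem —
the suite checks the trend, not an identity. `maxGroups` truncates the
path once a requested number of distinct groups has entered, which is
the economical way to ask "which genes enter first"; $\kappa$ is chosen
by inspecting model size along the path, not by cross-validation.

## Gene groups and data handling

Gene spans are 1-based fully-closed intervals (UCSC browser
convention): a SNP at position $p$ belongs to a span iff
$start \le p \le end$, span length is $end-start+1$, and spans shorter
than 500 bp are removed. Whether the original gene list used 0- or
1-based ends is not determinable from the method's description; the
closed convention is a documented choice, and boundary SNPs are tested
explicitly. Per symbol, the span runs from the minimum start to the
maximum end of its records; symbols spanning multiple chromosomes are
removed. Spans sharing at least one base are merged into one group whose
label joins the symbols with `":"` in genomic order; adjacent spans
(gap of zero bases) are *not* merged, and the test suite pins this
against a brute-force per-base oracle. Outside-gene SNPs with MAF
strictly above 0.01 become singleton groups; the rest are excluded.
Missing genotype calls are mean-imputed per SNP before fitting, while
MAF is always computed over non-missing calls only, so imputation leaves
allele frequencies untouched. $\tau$ defaults to 0.005.

## What the simulator emulates — and what it does not

`simulatePercData()` generates unrelated diploid individuals with
independent SNPs in Hardy–Weinberg proportions: genes laid out along one
chromosome (overlap injectable to exercise merging), rare MAFs uniform
on $[0.001, 0.005)$ and common MAFs on $[0.05, 0.5]$, 40% of each
gene's SNPs rare, and a trait
$y_i = \beta_{CV} x_{i,CV} + \beta_B b_{ig} + \varepsilon_i$ built from
one designated common variant and the raw rare burden of each causal
gene. The defaults — 500 individuals, 20 genes × 30 SNPs, burden effect
$0.8\sigma$, common effect $0.5\sigma$ — are the package's standing
study conditions for its recovery experiment. Optional covariate mode
layers age/sex/smoking/medication effects and repeated time points on
top so `residualize()` can be exercised end to end; otherwise the trait
is generated directly on the residual scale, mirroring the two-stage
analysis in which the trait handed to the regression is already a mean
residual.

What the simulator does **not** model: linkage disequilibrium (real
genotypes are correlated, which makes selection among neighbouring genes
harder than these tests suggest), family structure or kinship
(the method treats individuals as exchangeable; related samples inflate
test statistics), imputation error, and site-level missingness patterns.
Passing recovery tests therefore demonstrate correctness of the
machinery under idealized sampling, not field performance on cohort
data.

## Phenotype preparation

For repeated measurements, `residualize()` regresses the trait on
intercept, age, age², sex, smoking status and medication use, pooling
every time point of every individual as a separate observation, then
averages residuals within individual. The covariate list is
configurable since other traits need other adjustments. Records with a
missing trait or covariate are dropped (complete-case); medication is a
plain covariate, not a trait correction. No normality transform is
applied, and no mixed-model alternative is attempted — the mean residual
is the analysis trait by construction.

## Numerical choices and limitations

* Problem sizes in the tests and the reproduction script are chosen for
  a desk-scale run: oracle comparisons use $m = 50$ with at most 8
  columns (where an independent L-BFGS-B maximizer of an exactly split,
  smooth reformulation is trustworthy to well under the `1e-6`
  comparison tolerance), and the recovery experiment uses 50 replicates
  of the 500 × 600-SNP study conditions.
* `kappaMax()` is exact for the coordinate-wise stationarity of the
  zero solution under the tied parameterization; it is how the default
  grid is anchored. The at-zero entry test in the optimizer carries a
  few-ulp guard so that the boundary case — data gradient exactly equal
  to the penalty slope, as happens at $\kappa = \kappa_{max}$ — stays
  exactly empty instead of admitting rounding-noise coefficients.
* Ties and order: predictor order is deterministic (groups in genomic
  order, common variants by position, collapsed column last), so
  permutation of columns changes converged objectives only within
  numerical tolerance, which is tested.
* The weighting wording tension is inherited from the method as
  published: $\omega_c$ *increases* with MAF, so rarer common variants
  receive *smaller* penalty multipliers and are shrunk less. The
  formulas are implemented exactly as printed; no reinterpretation is
  attempted.
* $r_g$ multiplies $|\gamma_g|$ and $\gamma_g^2$ in the elastic-net
  terms but does not enter the group norm, again exactly as printed.
* The family-structure extension (generalized least squares with a
  kinship-derived covariance) is out of scope; so are binary traits,
  cross-validation for $\kappa$, LD-aware simulation, and
  variable-threshold searches over $\tau$.

## A worked example

```{r example, eval = FALSE}
cfg <- percSimConfig(nIndividuals = 300, nGenes = 10, snpsPerGene = 15,
                     seed = 42)
sim <- simulatePercData(cfg)
design <- buildDesign(sim$genotypes, sim$groups)
y <- trait(sim$phenotype)
path <- percFitPath(y, design, maxGroups = 5)
modelSizes(path)
groupInfo(design)$label[groupEntryOrder(path, design)]
```

The README shows this pipeline with the numbers it prints; the
`scripts/acceptance.R` script reruns the package's headline checks
(threshold arithmetic, optimizer-vs-oracle agreement, closed-form
limits, recovery rate) from scratch and writes them as JSON.
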