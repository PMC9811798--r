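---
title: "Omnibus weighted combination tests for gene-based association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Omnibus weighted combination tests for gene-based association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owc)
```

## The model

A gene holds $M$ SNPs with per-SNP association Z-scores
$\mathbf{Z} = (Z_1,\dots,Z_M)'$ from a GWAS summary file.  Under the null
of no association, $\mathbf{Z} \sim \mathrm{MVN}(\mathbf{0}, R)$ where $R$
is the linkage-disequilibrium (LD) matrix — the correlation matrix of the
genotype dosages, estimable from a reference panel of the same ancestry.
Any linearly weighted statistic $L(W) = W'\mathbf{Z}$ then has null
variance $W'RW$, and the corresponding score statistic
$S(W) = (W'\mathbf{Z})^2 / (W'RW)$ is $\chi^2_1$.

Four classical weightings cover the main genetic architectures:

* **burden** $L_B = \sum_m Z_m$ ($W = \mathbf{1}$): strongest when causal
  effects share one direction, collapses when they cancel;
* **weighted sum (WSS)** $L_W = \sum_m Z_m / \sqrt{p_m(1-p_m)}$ with
  $p_m$ the minor allele frequency: up-weights rarer variants
  (purifying-selection reasoning);
* **score** $S_S = \mathbf{Z}'R^{-1}\mathbf{Z}$: the supremum of $S(W)$
  over all weight vectors, attained at $W = R^{-1}\mathbf{Z}$, with a
  $\chi^2_M$ null;
* **sum of squares (SSU)** $S_Q = \mathbf{Z}'\mathbf{Z}$: a
  variance-component statistic robust to effect direction, with null law
  $\sum_i \lambda_i \chi^2_1$, $\lambda_i$ the eigenvalues of $R$.

The omnibus weighted combination (OWC) statistic takes their weighted
average on the 4-simplex,
$$
L_\rho = \rho_1 L_B^2 + \rho_2 L_W^2 + \rho_3 S_S + \rho_4 S_Q
       = \mathbf{Z}' A_\rho \mathbf{Z},
\qquad
A_\rho = \rho_1 \mathbf{1}\mathbf{1}' + \rho_2 WW' + \rho_3 R^{-1}
       + \rho_4 I,
$$
with $\rho_i \ge 0$, $\sum_i \rho_i = 1$.  For each fixed $\rho$ the null
law is the chi-square mixture with weights equal to the eigenvalues of
$R A_\rho$.  The test statistic is the minimum mixture p-value over a grid
of $\rho$ values (coordinates in $\{0, 0.1, \dots, 1\}$; 286 points), and
that minimum is calibrated by Monte Carlo: null scores
$\mathbf{Z}^{(b)} = D L^{(b)}$ with $DD' = R$ and $L^{(b)}$ i.i.d. standard
normal, and the add-one estimator
$\hat p = [\#\{T^{(b)} \le T_{\mathrm{obs}}\} + 1]/(B+1)$.  Setting
$\rho_2 = \rho_3 = 0$ recovers the burden/SSU family that underlies
SKAT-O; single vertices recover the four component tests exactly.

## Numerical choices

**Mixture tails.**  `mixture_sf()` offers two methods.  The default
(`"liu"`) is moment matching to a chi-square: closed form and vectorizable
over millions of statistics, which is what makes the Monte Carlo grid
search tractable; it is exact whenever all non-zero mixture weights are
equal (hence for the $\chi^2_M$ and scaled-$\chi^2_1$ vertex laws).  For
non-negative weights its skewness condition always selects the central
branch (a Cauchy–Schwarz consequence), and its absolute error in the mid
tail is of order $10^{-3}$ for the LD spectra used here.  That error is
immaterial for the OWC p-value itself, which is rank-based: the observed
and null statistics pass through the same approximation, so Monte Carlo
calibration is exact by exchangeability.  When the analytic tail value is
the quantity of interest (for example the S2T p-value at extreme
thresholds), `method = "imhof"` inverts the characteristic function
numerically (`"davies"` is accepted as an alias for this exact route).

**Eigenvalues of $RA$.**  The product is non-symmetric; eigenvalues are
computed from the symmetric similarity $R^{1/2} A R^{1/2}$, which
guarantees real output for positive semi-definite inputs.  Numerical
negatives above $-10^{-8}$ are clamped to zero.

**Inverse of $R$.**  LD pruning at $r^2 > 0.5$ is what keeps $R$
invertible in practice; as a numerical backstop, `ld_inverse()` escalates
to a ridge of $10^{-6}$ (logged, recorded in an attribute) when the
reciprocal condition number falls below $10^{-8}$.  Indefinite input
matrices are repaired by eigenvalue flooring followed by rescaling to unit
diagonal — deterministic and cheap, in place of a nearest-correlation
iteration.

**Per-gene precomputation.**  The 286 eigendecompositions and
moment-matching parameters are computed once per gene
(`owc_precompute()`) and reused for the observed statistic and every null
draw; with them in hand, each draw costs one $M$-vector of normals, four
quadratic forms, and 286 vectorized tail evaluations.  This is the
decision that makes $10^5$-replicate simulation studies run in seconds.

**Fast adaptive p-values.**  Genome scans spend most of their time on
unremarkable genes.  `adaptive_mc_pvalue()` starts with $B_0 = 10$ null
draws and multiplies the cumulative count by 10 per stage up to
$B_{\max} = 10^6$, reusing earlier draws, so the estimate is independent
of where stage boundaries fall.  Taken literally, a stop rule "report when
$\hat p > p_0$" applied to the add-one estimator can never continue past
the first stage (the estimator's floor $1/(B_0+1)$ already exceeds
$p_0 = 10^{-5}$), so the stopping decision here uses the raw exceedance
fraction — continue while *no* null statistic lies at or below
$T_{\mathrm{obs}}$ or while the estimate is still at the resolution floor —
while the reported value is always the add-one estimator on all
accumulated draws.  A pinned single stage reproduces `mc_pvalue()`
exactly under the same seed.

**Ties.**  Grid ties in the arg-min are broken by lexicographic grid
order; this affects only the reported best $\rho$, never $T$.

## Comparison tests

The sum test (ST) and squared sum test (S2T) are the burden and SSU
statistics under their comparator names.  The adaptive test (AT) searches
$Q_\rho = (1-\rho) Q + \rho B^2$ over the fixed one-dimensional grid
$(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1)$ and calibrates the minimum
p-value with the same Monte Carlo engine as OWC (seed-reproducible and
exact as $B \to \infty$), rather than by one-dimensional numerical
integration.  aSPU combines $\mathrm{SPU}(\gamma) = \sum_m Z_m^\gamma$ for
$\gamma = 1,\dots,8$ and $\mathrm{SPU}(\infty) = \max_m |Z_m|$; odd powers
are treated two-sidedly via $|\mathrm{SPU}|$, and per-power p-values come
from pooling the observed vector with the $B$ null draws, which makes the
final p-value uniform under the null by construction.

GATES computes $\min_j m_e \, p_{(j)} / m_{e(j)}$ with effective test
counts $m_e = M - \sum_{\lambda_i > 1} (\lambda_i - 1)$ from the
eigenvalues of the correlation matrix *of the p-values*.  We map genotype
correlation to p-value correlation with the procedure's fitted
sixth-degree polynomial before estimating $m_e$: using the absolute
genotype correlation directly overstates the dependence of two-sided
p-values and inflated the type-I error ratio to 1.3–1.6 at
$\alpha = 10^{-2}$ in our calibration runs, whereas the polynomial variant
sits at ratio $\approx 1.06$.  The estimator is a plug-in (`me_fun`) for
users who prefer a different one.

## The simulation harness

`synthetic_ld()` provides AR(1), exchangeable and two-block correlation
structures.  The default study gene used throughout the tests and the
acceptance script is an 11-SNP AR(1) matrix with parameter 0.5 — eleven
common SNPs with several strongly correlated pairs, the size and LD
profile of the EPB41 gene that motivates the design — with MAFs spaced
evenly over (0.067, 0.453), the common-variant range.  `sample_z()` draws
$\mathbf{Z} \sim \mathrm{MVN}(A \times \Delta, R)$: the null design uses a
zero mean; alternatives place sign $\times$ effect size at chosen causal
positions.  Distributional effect sizes (uniform on a closed interval, or
normal — "N(3,4)" is read as mean 3, *standard deviation* 4, with the
`sd` field making the variance convention explicit) are redrawn for every
replicate.

`type1_ratio()` and `power_estimate()` evaluate any registered test (or a
user function) over many replicates.  Monte Carlo tests share one sorted
null reference (`batch_null_reference()`) across all replicates of a
cell — statistically identical to per-replicate simulation under the
add-one estimator, and the only way large designs stay cheap.  For those
tests the reported `se_total` adds the reference-quantile noise
($\approx \sqrt{\alpha/B_{\mathrm{ref}}}/\alpha$ relative) to the binomial
replication noise; at $\alpha = 10^{-3}$ with a $2 \times 10^4$ reference
the reference term dominates, so calibration ratios at that design carry
a standard error near 0.25.

Problem sizes used by the shipped tests — $10^5$ null replicates for the
calibration ratios (the per-replicate-loop comparators use $2$–$3 \times
10^4$), 2000 replicates for power cells at $\alpha = 10^{-4}$, 2000 genes
with $B = 999$ for the uniformity check, $10^6$ draws for empirical tail
comparisons — are the package's choice of a scale at which every
assertion has a defensible Monte Carlo error bound.

## What the synthetic data does and does not show

The generator emulates the statistical structure of summary-based
association testing: correct null dependence ($\mathrm{MVN}(0, R)$),
mean-shifted alternatives, and realistic LD profiles.  It does not emulate
finite-sample non-normality of Z-scores, LD mismatch between the summary
cohort and the reference panel, allele-strand errors, or imputation
noise — so passing tests certify the method's distribution theory and
implementation, not robustness to those data pathologies.  In real
analyses the package assumes the LD matrix is allele-aligned to the
summary file (no harmonization is attempted), and mitigates estimation
error in $R$ the way practitioners do: drop MAF < 0.05, prune one of each
pair with $r^2 > 0.5$.  Pruning scans in genomic-position order by
default, which keeps the decision independent of the observed Z-scores
and hence leaves the null distribution untouched; a "keep the larger
$|Z|$" policy is available behind a flag.

## Known limitations

* No analytic p-value for the min-p statistic $T$; only the Monte Carlo
  estimator is defined, with resolution $1/(B+1)$.
* The Liu tail approximation, while calibration-neutral inside the Monte
  Carlo machinery, should not be quoted as an analytic tail probability
  below about $10^{-4}$; use `method = "imhof"` there.
* Genes with more than a few hundred SNPs after pruning make the per-gene
  eigendecomposition grid noticeably more expensive.
* Without MAFs the WSS component is undefined; the grid drops the
  $\rho_2 > 0$ points (logged) rather than substituting equal weights.
* Small-sample kurtosis corrections of the SKAT family are out of scope;
  the package targets the summary-statistic regime.
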