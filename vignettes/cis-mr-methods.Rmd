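---
title: "Methods for cis-Mendelian randomization with correlated instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods for cis-Mendelian randomization with correlated instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cis-Mendelian randomization (cis-MR) estimates the causal effect of an
exposure — typically protein expression, or a downstream biomarker proxying
it — on an outcome, using genetic variants from the single gene region that
encodes the protein. Unlike genome-wide MR, all candidate instruments come
from one locus and are strongly correlated through linkage disequilibrium
(LD). Two consequences dominate the statistics:

* the correlated-instruments IVW estimator needs the inverse of an LD-based
  weighting matrix, which becomes numerically unstable when highly
  correlated variants are included; and
* with few truly independent signals in the region, instruments can be
  weak, biasing two-sample estimates toward the null.

`cismr` implements the method families used in practice for this setting,
under a common two-sample summary-data interface: per-variant
variant–exposure associations $(\hat\beta_{Xj}, \hat\sigma_{Xj}, p_{Xj})$
from one sample of size $N_1$, variant–outcome associations
$(\hat\beta_{Yj}, \hat\sigma_{Yj})$ from an independent sample of size
$N_2$, and a reference LD correlation matrix $R = (\rho_{ij})$ with effect
allele frequencies $f_j$.

## Estimators

**Wald ratio (top SNP).** With a single instrument,
$\hat\theta = \hat\beta_Y/\hat\beta_X$ with first-order standard error
$\hat\sigma_Y/|\hat\beta_X|$. Simple and immune to LD, but it ignores all
secondary signals in the region and is exposed to winner's curse when the
same sample picks the variant and estimates its effect.

**IVW with correlated instruments.** The generalised least squares form
$$\hat\theta_{\mathrm{cor}}
  = (\hat\beta_X^{\top}\Omega^{-1}\hat\beta_X)^{-1}
    \hat\beta_X^{\top}\Omega^{-1}\hat\beta_Y,\qquad
  \mathrm{se}^2 = (\hat\beta_X^{\top}\Omega^{-1}\hat\beta_X)^{-1},$$
with weighting matrix $\Omega_{ij} = \hat\sigma_{Yi}\hat\sigma_{Yj}\rho_{ij}$,
the covariance of the outcome associations under LD. We solve through the
Cholesky factor of $\Omega$ and refuse matrices whose condition number
exceeds `max_condition` (default $10^8$) instead of falling back to a
pseudo-inverse: a silent pseudo-inverse would mask exactly the instability
this estimator is known for. Fixed-effect form only; confidence intervals
use the normal quantile $1.959964$ and p-values are two-sided normal.

**LD-pruning** (`ld_prune`) greedily selects the remaining variant with the
smallest exposure p-value (optionally requiring $p < \tau$) and discards
everything correlated with it at $|\rho| \ge$ `rho`. Ties on the p-value are
broken by the smaller exposure standard error, then lexicographic id, making
the procedure fully deterministic. Note that the selected set is *not*
monotone in `rho` in general: raising the threshold can admit an earlier
variant that then prunes a variant selected at the lower threshold. The
guaranteed invariants are that every input variant is either selected or
discarded with a reason, and all pairwise $|\rho|$ among selected variants
are below `rho`.

**Conditional-and-joint selection** (`cojo_select`) replaces marginal
p-values with conditional ones reconstructed from summary statistics: using
HWE genotype variances $2f_j(1-f_j)$ and the reference LD, the normal
equations of the joint regression are rebuilt as
$X^{\top}X = N_1\,D^{1/2} R D^{1/2}$ and
$X^{\top}y = N_1\, d_j \hat\beta_{Xj}$, with the residual variance
re-estimated after every joint fit (floored at $10^{-8}$) and the exposure
variance taken as `var_y` (default 1, standardized trait). Candidates
correlated above `rho` with the selected set are screened out; the add step
requires the smallest conditional $p < \tau$, the drop step removes the
largest joint $p > \tau$. A single exposure sample size is assumed
throughout.

**Principal-components IVW** (`pca_ivw`) eigendecomposes
$\Psi_{ij} = \hat\beta_{Xi}\hat\beta_{Xj}\,\rho_{ij}/
(\hat\sigma_{Yi}\hat\sigma_{Yj})$ — a precision-weighted version of $R$
that prioritizes well-measured variants — and evaluates the IVW estimate in
the coordinates of the first $k$ eigenvectors, where $k$ is the smallest
number of components explaining `threshold` (0.99 or 0.999 by convention)
of the $\Psi$ trace. At full rank this is algebraically the correlated IVW;
truncation is what restores numerical stability. $\Psi$ is symmetrized
before decomposition, numerically negative eigenvalues below
$10^{-10}\lambda_{\max}$ are clamped to zero, and $k$ is floored at 1.

A useful identity guided several design choices below. Because
$\Omega_X = \mathrm{diag}(\hat\sigma_X) R\, \mathrm{diag}(\hat\sigma_X)$ and
$\Omega_Y$ differ only by the scalar
$c = (N_2 \sigma_X^2)/(N_1 \sigma_Y^2)$, the noise term in the IVW
denominator satisfies
$\mathrm{tr}(\tilde\Omega^{-1}\tilde W^{\top}\Omega_X \tilde W) = c\,k$, so
the expected attenuation of the PCA estimate is
$$\frac{\hat\theta}{\theta} \approx \frac{1}{1 + k/(N_1 v_G)},$$
with $v_G$ the exposure variance explained by the region. The bias of
PCA-IVW is therefore controlled by the number of retained components
relative to $N_1 v_G$, not by the number of variants.

**JAM** (`jam_fit`) performs Bayesian stochastic search over variant
subsets from the summary-data likelihood of $z_j = 2f_j(1-f_j)N_1
\hat\beta_{Xj}$ (approximating $G^{\top}X$) with
$G^{\top}G \approx N_1 D^{1/2} R D^{1/2}$ from the reference panel. Under a
conjugate normal-inverse-gamma g-prior, each subset's marginal evidence is
closed-form, and a reversible-jump chain proposing add / delete / swap moves
(equal probability among the feasible moves, with the proposal-asymmetry
correction) samples the model posterior, starting from the smallest-p
variant. Hyperparameters: unit-information $g = N_1$; beta-binomial model
prior $(1, P)$ giving a prior mean model size near one, matching the
fine-mapping convention of sparse independent signals; inverse-gamma
(0.01, 0.01) on the residual variance; the exposure is treated as
standardized ($y^{\top}y = N_1$). Ill-conditioned subsets (condition
$> 10^8$, estimated from the Cholesky diagonal) are unvisitable
($-\infty$ evidence), which is why a pre-pruning step at `preprune_rho`
(default 0.9, no significance threshold) precedes the search. The causal
estimate is the posterior-weighted average of per-model correlated-IVW
estimates, with the law of total variance supplying the standard error;
weights are renormalized over non-empty models and the null-model mass is
reported separately, keeping the estimator defined whenever any instrument
has support. Binary outcomes can be mapped to the linear scale with
`logodds_to_linear` ($\beta\,\bar y(1-\bar y)$ at case fraction $\bar y$).

**Factor-based methods** (`fit_factors`, `f_liml`, `ar_test`, `lm_test`,
`clr_test`). The instruments are the leading $k$ eigenvectors of the
rescaled covariance $\mathrm{diag}(s) R\, \mathrm{diag}(s)$,
$s_j = \sqrt{2f_j(1-f_j)}$ — automatic $k$ keeps 99% of the trace. The
moment function is
$\hat g(\theta) = \tfrac1P \Lambda^{\top} D (\hat\beta_Y -
\theta\hat\beta_X)$, with one reference panel supplying $D = D_X = D_Y$.
F-LIML minimizes the continuously-updated criterion
$\hat g(\theta)^{\top} V(\theta)^{-1} \hat g(\theta)$ with the delta-method
variance $V(\theta) = \tfrac1{P^2}\Lambda^{\top} D(\Omega_Y +
\theta^2\Omega_X)D\Lambda$ (coarse grid bracket, then golden-section /
parabolic refinement to $10^{-9}$); the standard error comes from the
curvature $(A^{\top}V^{-1}A)^{-1}$, $A = \tfrac1P\Lambda^{\top}D
\hat\beta_X$. The weak-instrument-robust tests use the same pieces: AR is
$\hat g^{\top}V^{-1}\hat g \sim \chi^2_k$; LM is the Kleibergen score with
the orthogonalized derivative $\tilde D = -A - \theta\,M_X V^{-1}\hat g$
($\chi^2_1$); CLR combines the two with Moreira's conditional null,
evaluated by seeded Monte Carlo (10,000 draws by default). With $k = 1$ the
three statistics coincide and the CLR p-value is computed exactly from
$\chi^2_1$, so CLR = AR identically. Confidence sets come from test
inversion on a grid (default 801 points on $[-2, 2]$), sharing the Monte
Carlo draws across grid points so the p-value curve is smooth; sets may be
empty, disjoint, or unbounded within the grid, and are flagged as such.

## The synthetic-data generator

`region_spec` + `generate_genotypes` build a synthetic gene region:
haplotypes are latent Gaussian vectors thresholded at the allele-frequency
quantile, dosages the sum of two independent haplotypes. Two within-block
structures exist:

* **autoregressive**: latent correlation `decay^|i-j|` within a block
  (the latent matrix is used as-is, so dosage correlations are attenuated
  by the dichotomization);
* **clustered** (the scenario default): each block is a set of clusters of
  near-duplicate variants — within-cluster dosage correlation `within_r`
  (default 0.998), across clusters `between_r`, stated *on the dosage
  scale* and enforced by inverting the dichotomization (a one-dimensional
  tetrachoric root-find per level; allele frequency is constant within a
  block, as near-perfect LD implies near-equal frequencies).

The clustered form is the deliberate choice for the shipped scenarios. Real
gene regions genotyped at scale contain long runs of variants in almost
perfect LD, so a region with hundreds of variants has only a dozen or two
effective dimensions; by the attenuation identity above, that effective
rank — not the variant count — is what governs the behaviour of PCA-IVW
and the factor methods. The default region (60 variants, 6 blocks of 10,
clusters of 6+4, `between_r` 0.6 for the dense "shbg"-like region and 0.8
for the "hmgcr"-like one) reproduces an effective rank of roughly 12–18 at
the 99.9% level, matching the regime implied by large-biobank LD, while an
autoregressive block would spread its spectrum over nearly all 60
dimensions — a regime no amount of rescaling can repair.

Scenarios (`mr_scenario`) follow a two-sample design with confounding:
$$X = \textstyle\sum_j b_{Xj} G_j + U + \epsilon_X,\qquad
  Y = \theta X + U + \epsilon_Y,\qquad
  U,\epsilon_X,\epsilon_Y \sim N(0, \sigma_0^2)\ \text{iid},$$
with six causal variants (one per block, at the block centre), causal
effects $|N(0, s)| + c$ for the risk-increasing allele ($s = 0.2$,
$c = 0.1$ "shbg"-like; $s = 0.03$, $c = 0.03$ "hmgcr"-like), rescaled so
the causal variants explain exactly $v_G$ of the exposure variance (3% / 2%
in the strong-instrument scenarios, one tenth of that in the weak ones).
Unit confounder loadings with $\sigma_0^2 = (1 - v_G)/2$ make
$\mathrm{Var}(X) = 1$; only $v_G$ is pinned by the emulated studies, and
the oracle F statistic of the regression of $X$ on the six causal dosages
then has mean $\approx 1 + N_1 v_G / ((1 - v_G)\,6)$ — about 52, 35 and
6.0 for the three shipped settings at $N_1 = 10{,}000$.

Samples are drawn by bootstrap: one reference pool of `nref` individuals
(default 50,000) is generated per scenario; every replicate resamples
exposure ($N_1 = 10{,}000$) and outcome ($N_2 = 180{,}000$) individuals
with replacement from the pool, and the reference LD matrix is computed
once from the entire pool — mirroring a design in which both GWAS samples
and the LD panel derive from one biobank. Two exact shortcuts keep this
fast: per-variant marginal regressions are computed from pool-length
weighted cross-products (no per-replicate genotype matrix is materialized),
and the exposure-side noise entering the outcome sample is drawn as a
single normal with the analytically summed variance
$((\theta+1)^2 + \theta^2 + 1)\sigma_0^2$.

**What the generator does not emulate:** binary outcomes (the outcome is
continuous, with $N_2$ playing the case-control-scale role), pleiotropy,
population structure, strand ambiguity, per-variant sample-size variation,
and real LD's long-range decay patterns. Passing benchmarks therefore
demonstrate correctness of the estimators and calibration machinery under
the stated generating model — not robustness to the biases those real-data
features introduce.

## The benchmark harness

`run_benchmark` runs a method battery over replicates (all methods see the
same data within a replicate, via per-replicate seeds derived from one
master seed) and tabulates median estimate and standard error, type-I error
(null scenarios), coverage of the 95% interval, power (non-null), failure
counts, and the mean oracle F. A method that fails on a replicate — empty
selection under $\tau$, ill-conditioned weighting matrix — is excluded
from that replicate with the failure counted; a method failing everywhere
yields an NA row rather than an error. Pruning-type selectors use the GWAS
threshold $\tau = 5\times10^{-8}$ in strong-instrument scenarios and
$\tau = 10^{-3}$ in weak ones, where genome-wide significance is often
unattainable.

## Problem sizes and numerical choices

* Benchmarks and the acceptance script use 1000 replicates for calibration
  and coverage quantities; the parameter-recovery and weak-instrument
  pattern checks in the test suite use 300 replicates, and the AR/CLR
  weak-null calibration check 250 — medians and proportions are stable at
  these sizes, and the full suite runs on a single CPU in well under half
  an hour.
* JAM chains inside the benchmark run 3000 iterations with 300 burn-in:
  after pre-pruning the default region to ~12 variants the posterior
  concentrates on a handful of models and visit frequencies stabilise
  quickly. `jam_config()`'s own default remains 1,000,000 iterations with
  10% burn-in for standalone analyses. Chains are exactly reproducible
  given `seed`, and evidence values are cached per visited model.
* Condition-number guards: $10^8$ throughout (IVW, PCA projection, JAM
  submodels, CoJo). Symmetric eigen-decompositions are applied to
  explicitly symmetrized matrices; negative eigenvalues from rounding are
  clamped (PSD validation tolerates $-10^{-8}$).
* LD files: asymmetries up to $10^{-6}$ are averaged away, larger ones are
  errors; diagonals must be 1 to $10^{-6}$.
* Reference pools of 50,000 individuals make LD estimation error
  (SE $\approx 0.0045$ per correlation) negligible for every method; the
  small-reference regime can be studied with `ref_per_rep` in
  `run_benchmark`.

## Known limitations

* The weighting matrix convention $\Omega_{ij} =
  \hat\sigma_{Yi}\hat\sigma_{Yj}\rho_{ij}$ treats the exposure
  associations as fixed; no random-effects inflation for pleiotropy is
  offered (pleiotropy-robust estimators are out of scope).
* The F-LIML weighting is the package's delta-method construction; other
  weightings of the same moment function are admissible and would differ
  in finite samples, though all are first-order equivalent.
* `cojo_select` assumes one exposure sample size for all variants and HWE
  genotype variances; panels with per-variant $N$ need external
  harmonization first.
* Harmonization does no strand inference from allele frequency; palindromic
  variants are either kept or dropped wholesale.
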