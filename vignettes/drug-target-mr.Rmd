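---
title: "Drug-target Mendelian randomization with mrtarget: models, defaults, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target Mendelian randomization with mrtarget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtarget)
```

## 1. The statistical model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables. For variant $j$ we observe, from two non-overlapping GWAS, the
estimated per-allele effect on the exposure $\hat\beta_{Xj}$ (SD units for a
quantitative trait) with standard error $\sigma_{Xj}$, and on the outcome
$\hat\beta_{Yj}$ (log-odds for a binary trait) with $\sigma_{Yj}$. Under the
instrumental-variable assumptions (relevance, exchangeability, exclusion
restriction), each valid instrument satisfies
$\beta_{Yj} = \theta\,\beta_{Xj}$, and $\theta$ — the causal log-OR per
exposure SD — is the estimand.

*Drug-target* MR restricts instruments to a cis window around the gene
encoding a drug target, so $\theta$ approximates the effect of
pharmacological perturbation of that target rather than of the exposure by
any mechanism. The package models the canonical use case of a very large
lipid GWAS exposure against rare congenital-outcome case/control panels,
reporting odds ratios per 1 SD *lower* exposure (the direction a lowering
drug moves it).

### Estimators

**IVW.** The primary estimator is the weighted-least-squares slope through
the origin,
$\hat\theta = \sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj} \big/ \sum_j w_j \hat\beta_{Xj}^2$
with $w_j = \sigma_{Yj}^{-2}$; its fixed-effect standard error is
$(\sum_j w_j\hat\beta_{Xj}^2)^{-1/2}$. Heterogeneity is summarized by
Cochran's $Q = \sum_j w_j(\hat\beta_{Yj} - \hat\theta\hat\beta_{Xj})^2$.
The default variance model is *multiplicative random effects*: the SE is
inflated by $\max\{1, \sqrt{Q/(k-1)}\}$, never deflated. Inference is
normal. With a single instrument IVW reduces to the Wald ratio
$\hat\beta_{Y}/\hat\beta_{X}$ with first-order SE
$\sigma_Y/|\hat\beta_X|$.

**MR-Egger.** Weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$
with a free intercept after orienting every instrument to
$\hat\beta_{Xj}\ge 0$. Under the InSIDE condition (instrument strength
independent of direct effects) the intercept estimates the average
directional pleiotropy and the slope remains consistent for $\theta$.
Residual dispersion is floored at 1 (multiplicative model) and inference
uses $t_{k-2}$. The $t_{k-2}$ choice is corroborated empirically: the
package's fixtures of published sensitivity estimates reproduce their
printed Egger p-values under $t_{k-2}$ at the panel instrument counts
(k = 2014, 22, 5) to within input-rounding error, while a normal reference
does not (see `tests/testthat/test-acceptance.R`). Published *intercept*
p-values match neither reference exactly; the package does not chase them
and records the reference used in `df_used`.

**Weighted median.** Per-instrument ratios $\hat\beta_{Yj}/\hat\beta_{Xj}$
with weights $\propto \hat\beta_{Xj}^2/\sigma_{Yj}^2$; the estimate
linearly interpolates between the order statistics whose cumulative
midpoint weights bracket 0.5. It is consistent when at least half the
weight comes from valid instruments. The SE comes from a parametric
bootstrap (both sides redrawn from $N(\hat\beta, \sigma)$; default 1000
replicates, seed 2024).

Sensitivity estimators require $k \ge 3$ instruments; below that they
return an explicit *unavailable* marker (not an error), so a grid run can
report "unavailable (<3 SNPs)" cells.

### Instrument strength

Per SNP, $F_j = (\hat\beta_j/\sigma_j)^2$ and $R_j^2 = F_j/(N-2+F_j)$;
combined, $R^2 = \sum_j R_j^2$ and $F = \frac{n-k-1}{k}\cdot\frac{R^2}{1-R^2}$
with $n$ the exposure study size and $k$ the instrument count. $F < 10$
raises the conventional weak-instrument flag. In the two-sample setting
weak instruments bias toward the null, so the flag marks reduced power and
attenuation rather than spurious signal.

### Colocalization

An MR signal in a cis region can reflect a shared causal variant or
distinct variants in LD. For each variant the package computes Wakefield's
approximate Bayes factor in log form,
$\log\mathrm{ABF} = \tfrac12\log\frac{V}{V+W} + \tfrac{z^2}{2}\frac{W}{V+W}$
($V = \sigma^2$, $z = \hat\beta/\sigma$, prior effect variance $W$), and
enumerates the five single-causal-variant hypotheses: H0 (no association),
H1/H2 (one trait only), H3 (distinct variants), H4 (shared variant), with
per-variant priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and prior
effect SDs $\sqrt W$ = 0.15 (quantitative) / 0.20 (log-odds) — the
canonical defaults of the method, all exposed in `coloc_priors()`. All
hypothesis sums are accumulated by log-sum-exp because a single
genome-wide-significant variant already overflows `exp()` in double
precision. If rounding drives the H3 cross-term negative it is clamped to
zero with a warning; single-variant regions carry no H3 mass structurally.

### Multiple testing

`bh_adjust()` implements the Benjamini–Hochberg step-up rule. The default
family is *per exposure* across its outcome panel (a global family is
configurable): each exposure's primary IVW p-values are adjusted together,
mirroring how a drug-target panel of related malformation outcomes is
reported. Failed cells are excluded from the family rather than imputed.

## 2. Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `p_threshold` | 5×10⁻⁸ (strict `<`) | — | genome-wide significance |
| `r2_threshold` | 0.1 | LD r² | uncorrelated-instrument convention |
| region flank | 10 kb (GWAS), 100 kb (pQTL/eQTL use) | bp | wider cis window buys power when the molecular GWAS is small |
| `palindromic_eaf_window` | 0.08 | allele frequency | A/T and G/C variants with eaf in [0.42, 0.58] on either side cannot be strand-resolved; conservative drop |
| IVW `variance_model` | multiplicative random | — | robust to over-dispersion, never anti-conservative |
| Egger reference | $t_{k-2}$ | — | matches published tables (above) |
| `n_boot` / `seed` | 1000 / 2024 | — | weighted-median bootstrap |
| coloc priors | 1e-4 / 1e-4 / 1e-5; $\sqrt W$ 0.15 / 0.20 | — | canonical ABF defaults |
| `fdr_alpha` | 0.05 | — | expected FDR |
| weak-instrument line | F < 10 | — | standard rule of thumb |

Harmonization conventions: variants are matched by identifier only (shared
rsID namespaces; positions differ across genome builds); coordinates are
1-based inclusive with closed windows; missing frequencies disable
frequency-based resolution, so palindromic variants are then always
dropped. Complementary-strand matches that additionally need an
orientation swap are recorded under the single action `strand_flipped`
(the beta is negated as required); allele pairs incompatible under every
orientation are discarded with a warning and counted in an attribute.
Selection ties on p-value break by ascending variant id, making pruning
fully deterministic.

## 3. The synthetic world

`simulate_two_sample()` draws, per variant: MAF ~ U(0.05, 0.5); true
per-allele exposure effects rescaled so
$\sum_j 2\,\mathrm{maf}_j(1-\mathrm{maf}_j)\beta_{Xj}^2$ equals the stated
`exposure_r2` (exposure variance 1); observed effects
$N(\beta, \sigma)$ with the normal-theory SEs
$\sigma_{Xj} = (2\,\mathrm{maf}_j(1-\mathrm{maf}_j)\,n_X)^{-1/2}$ and, for
the binary outcome,
$\sigma_{Yj} = (2\,\mathrm{maf}_j(1-\mathrm{maf}_j)\,n\,\phi(1-\phi))^{-1/2}$
with case fraction $\phi$. True outcome effects are
$\theta\beta_{Xj} + \alpha_j$, where the direct effects $\alpha_j$ are
drawn independently of instrument strength — InSIDE holds by construction
— with mean 0 (balanced) or `pleiotropy_mean` (directional). Defaults
mirror the motivating design: $n_X$ = 1,320,016; 360 cases vs 307,206
controls; 100 variants explaining 10% of exposure variance. Effect alleles
are coded exposure-increasing ($\beta_{Xj}\ge 0$), the usual convention in
drug-target instrument tables; this is what makes "directional" pleiotropy
a well-defined direction after Egger's orientation step. One integer seed
drives deterministic per-stage sub-streams, and the generator restores the
caller's RNG state.

What it does *not* emulate — and therefore what a green test does not
establish: real LD panels (LD is block-exchangeable and is *stated*, not
injected into the sampling noise of the association estimates, so pruning
logic is exercised but LD-induced correlation of errors is not); sample
overlap between the two GWAS; population stratification; allele-frequency
differences between studies; misreported or multi-allelic sites. The
published instrument counts for real genes (e.g. 2014 genome-wide LDL
SNPs, 22 cis SNPs) depend on the real LD reference and are not
reproducible here. `simulate_coloc_region()` *does* propagate planted
signals through an exchangeable LD matrix, including correlated noise via
its Cholesky factor.

## 4. Numerical and design choices

* **Log-space colocalization** throughout; the H3 term uses
  `log1p(-exp(l12 - l1 - l2))` with an explicit clamp at 0.
* **Bootstrap determinism**: the weighted-median bootstrap runs under a
  locally-set seed and restores the caller's RNG state, so pipeline runs
  are bit-for-bit reproducible from the config seed.
* **`n_boot = 0`** skips the bootstrap and returns `NA` SE/p — used in
  simulation loops that only need point estimates.
* **Degenerate inputs**: `beta_exp = 0` is a hard error for the Wald
  ratio; all-equal exposure effects are a collinearity error for Egger;
  empty harmonized intersections and zero-survivor selections raise
  explicit no-instrument errors, which the grid runner records per cell
  instead of aborting.
* **Config files are JSON**, not YAML: the target environment provides
  `jsonlite` but no YAML parser, and the schema is structure-identical.

### Calibration-test design (fixed before the simulations were run)

* *Egger type-I error* is checked with constant outcome SEs, under which
  the floored multiplicative-dispersion $t_{k-2}$ test is exactly
  calibrated; with MAF-varying SEs the multiplicative model is only an
  approximation to the additive pleiotropy variance and the test can
  deviate from nominal — a known property of the estimator, not a bug.
* *Weighted-median robustness* uses 20 equal-strength instruments with 8
  carrying large one-sided direct effects, so invalid weight is exactly
  40%. The weighted median then targets the $0.5/0.6$ weighted quantile
  of the valid ratio distribution — a finite-sample shift of order the
  ratio noise that does not average away over replicates. Robustness is
  therefore asserted in absolute terms at the simulated noise level (bias
  < 0.1 on $\theta = 0.3$, and < 15% of the IVW pleiotropy bias of ≈ 2),
  not as "within Monte-Carlo error of the mean", which no fixed noise
  level can satisfy.
* *Null calibration* of the 1×9 grid aggregates 30 replicate runs (270
  cells) so the binomial bands on the 5% rejection rate are meaningful.

## 5. Known limitations

* Correlated instruments are not supported (no generalized IVW); pruning
  below r² = 0.1 is assumed sufficient.
* The binary-outcome SE approximation treats case fraction as constant
  across variants; fine for rare outcomes, cruder for common ones.
* Colocalization assumes at most one causal variant per trait per region;
  multi-signal regions dilute PP(H4).
* The weighted-median bootstrap is parametric; with very few instruments
  its SE can understate uncertainty.
* No liftover, VCF parsing, multi-allelic handling, or phenome-wide
  scanning; LD must be supplied (or simulated), never computed from
  genotypes.
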