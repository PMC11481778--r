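---
title: "Drug-target cis-MR with correlated instruments: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target cis-MR with correlated instruments: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismr)
```

## The problem

Cholesteryl-ester-transfer-protein (CETP) inhibitors and similar drugs act by
lowering the concentration or activity of a single protein. Genetic variants
in and around the gene encoding that protein shift its level for a lifetime,
so they act as natural mini-trials of pharmacological inhibition:
*cis*-Mendelian randomization (cis-MR) uses them as instrumental variables to
estimate the causal effect of the protein on downstream outcomes from two
GWAS summary-statistics tables — one for the exposure protein, one for the
outcome — without individual-level data. Restricting instruments to the
gene's own locus limits horizontal pleiotropy by construction, but leaves
instruments in strong mutual linkage disequilibrium (LD), which the
estimator must model.

`cismr` implements the complete analysis: instrument selection in a
gene-centred window, LD-aware generalized-least-squares (GLS) estimation,
heterogeneity-based outlier pruning, data-driven choice between the IVW and
MR-Egger estimators, and presentation-layer reporting. A synthetic
two-sample GWAS generator with known ground truth makes every stage testable
offline.

## The estimators

Let $\hat\beta_{Xj}, \hat\beta_{Yj}$ be the marginal exposure and outcome
associations of instrument $j$ with standard errors $\sigma_{Xj},
\sigma_{Yj}$, and $R$ the signed LD (correlation) matrix of the instruments
from a reference panel. Because all outcome betas come from one GWAS, their
sampling covariance is approximately

$$\Omega_{jk} = \sigma_{Yj}\,\sigma_{Yk}\,R_{jk}.$$

**GLS-IVW** fits $\hat\beta_Y = \alpha\,\hat\beta_X$ by generalized least
squares:

$$\hat\alpha = \frac{\hat\beta_X^\top \Omega^{-1} \hat\beta_Y}
                    {\hat\beta_X^\top \Omega^{-1} \hat\beta_X},
\qquad
\mathrm{se}(\hat\alpha) = (\hat\beta_X^\top \Omega^{-1} \hat\beta_X)^{-1/2},$$

reducing exactly to the classic fixed-effect meta-analysis of per-variant
Wald ratios when $R = I$, and to the single Wald ratio
$\hat\beta_Y/\hat\beta_X$ when $J = 1$.

**GLS MR-Egger** first orients every variant so $\hat\beta_{Xj} \ge 0$
(flipping $\hat\beta_{Xj}$, $\hat\beta_{Yj}$ and the signs of row/column $j$
of $R$ — estimates are invariant to this re-labelling, which the test suite
checks), then fits $\hat\beta_Y = \beta_0 + \alpha\,\hat\beta_X$ with the
same $\Omega$. The intercept $\beta_0$ absorbs *average directional
pleiotropy*; the slope remains a causal estimate when pleiotropy is
balanced about a constant.

Heterogeneity is Cochran's $Q = r^\top \Omega^{-1} r$ with $r$ the fitted
residual, on $J-1$ (IVW) or $J-2$ (Egger) degrees of freedom. Confidence
intervals use the fixed multiplier 1.96 throughout, matching the 95% CI
convention of drug-target MR reports.

### Leverage, outliers, pruning

Pleiotropic or mismodelled variants surface either as dominant points of the
GLS fit or as heterogeneity. Leverage is the diagonal of the (oblique) GLS
hat matrix $H = X(X^\top\Omega^{-1}X)^{-1}X^\top\Omega^{-1}$; it sums to the
number of fitted parameters, so the mean leverage is $p/J$. The per-variant
outlier statistic is the squared $j$-th *whitened* residual, whitening by
the inverse lower-triangular Cholesky factor of $\Omega$ with variants kept
in genomic order. This definition was chosen because it makes the
decomposition $\sum_j q_j = Q$ exact under LD, which is what a
$\chi^2_1$-type cutoff presumes; any other attribution (e.g. marginal
standardized residuals) double-counts correlated variants. Pruning removes
variants with leverage above 3× the mean or outlier statistic above
$\chi^2_1(0.001) = 10.83$, one worst offender at a time (largest outlier
statistic, ties by leverage then position) with a refit between removals —
leverages and residuals change after each removal, so one-at-a-time is the
conservative, deterministic choice. Pruning runs under the IVW fit, and both
estimators are then fitted on the common pruned set so their $Q$ statistics
are comparable; a per-estimator alternative would make the $Q$ difference
below ill-defined.

### Model selection

Egger buys robustness with precision; whether it is needed is decided from
the data: $Q_{\mathrm{IVW}} - Q_{\mathrm{Egger}} \sim \chi^2_1$
approximately under no directional pleiotropy, so Egger is selected iff the
difference strictly exceeds the $1-\alpha_{\mathrm{select}}$ quantile
(default $\alpha_{\mathrm{select}} = 0.05$, exposed as an argument since the
level is a judgement call).

## Instrument selection defaults

| parameter | default | units | why |
|---|---|---|---|
| `flank` | 25,000 | bp | gene-body ± flank window; anchoring on the gene body, not its midpoint, keeps the window meaningful for genes of any length |
| `f_min` | 24 | — | minimum per-variant $F = (\hat\beta_X/\sigma_X)^2$, the summary-statistic approximation; limits weak-instrument bias |
| `maf_min` | 0.01 | frequency | below this, reference-panel LD estimates are unreliable |
| `r2_max` | 0.30 | $r^2$ | clumping ceiling: keeps some LD (power) while avoiding near-collinear $\Omega$ |
| `leverage_mult` | 3 | × mean | leverage pruning cutoff |
| `outlier_max` | 10.83 | $\chi^2$ | $\chi^2_1$ upper 0.001 critical value |
| `alpha_select` | 0.05 | level | Q-difference selection |
| `bonferroni_m` | 29 | tests | family size of the primary outcome panel |

Filters run before clumping (weak variants should not shield strong ones
from thinning); the stage order and per-stage counts are written to the fit
log. Clumping ranks by exposure p-value (ascending, ties to the smaller
position) — the universal greedy convention.

Harmonization matches variants by id with a chromosome:position fallback,
drops multi-allelic collisions, and resolves strand/swap ambiguity from the
alleles; palindromic variants (A/T, C/G) default to frequency-based
inference (`infer-by-eaf`: agree within ±0.08, drop when MAF > 0.42), with
`drop-ambiguous` available for the conservative reviewer. Neither policy is
claimed to be "the" field standard; both are exposed.

If the estimated LD matrix is not positive definite (duplicated variants,
small panels), it is shrunk towards the identity with the smallest
$\lambda \in \{0.001, 0.005, 0.01, 0.05\}$ that restores a smallest
eigenvalue above $10^{-8}$; $\lambda$ is recorded in the fit log.

## What the generator simulates

`simulate_two_sample()` draws a cis locus and two non-overlapping GWAS
samples:

* **Genotypes.** Haplotypes are latent standard normals with block-AR(1)
  correlation (`within_block_rho^|i-j|`), thresholded at each variant's
  MAF quantile; dosage = sum of two independent haplotypes. This gives exact
  control of MAF and (through `latent_rho_for()`, which inverts the
  attenuation caused by thresholding) of dosage-scale LD, at desk scale —
  unlike a coalescent simulation it makes no claim to realistic haplotype
  diversity or recombination maps.
* **Exposure.** $x = G\gamma + e$, unit variance, with the locus explaining
  `h2_exposure` (default 0.5) of the trait — a strong cis-pQTL regime, as
  plasma proteins with druggable cis loci typically show. The default
  $\gamma$ decays geometrically (factor 0.85) with alternating signs: one
  lead signal plus weaker secondaries, so fixtures contain per-variant F
  statistics on both sides of the 24 threshold.
* **Outcome.** A disjoint sample: $y = \alpha x + G\delta + e$ (continuous,
  unit variance) or a logistic liability model with the intercept solved to
  hit `case_fraction`. $\delta \ne 0$ injects direct (pleiotropic) effects;
  a constant $\delta$ is directional pleiotropy targeted at the Egger
  intercept.
* **Summary statistics.** Per-variant single-variant least squares
  (continuous) or the logistic score approximation (binary), vectorized;
  the analytic dosage covariance (a bivariate-normal orthant integral)
  provides exact `truth$true_marginal` for oracle tests.

Defaults mirror the motivating study design: exposure GWAS n = 4,248,
reference panel of 5,000 individuals, large outcome GWAS, 20 variants in
blocks of 5 inside a ±25 kbp window on chromosome 16.

What passing tests on these data do **not** show: realism of LD beyond
block-AR(1), allele-frequency spectra, sample overlap, population
stratification, or winner's-curse from discovery-based instrument choice.
Binary outcomes use marginal logistic effects, so the fitted log-odds slope
is mildly attenuated by non-collapsibility relative to the generating
conditional $\alpha$ (documented in the binary recovery test, which uses a
common-disease fraction of 0.1 and a 10% tolerance).

## Monte-Carlo problem sizes

The statistical checks in the test suite use: 500 replicates at
(J = 20, n\_exposure = 5,000, n\_outcome = 100,000) for parameter recovery;
1,000 replicates under the null and 500 per pleiotropy arm at
n\_outcome = 20,000 — the nominal level of the slope test and the
sign/selection behaviour of the Egger intercept do not depend on the
outcome sample size, so the smaller size is used there. One reference panel
is simulated per experiment and shared across replicates, exactly as a real
reference cohort would be.

## Known limitations

* **First-order weights under a small exposure GWAS.** $\Omega$ models
  outcome-beta noise only; exposure betas are treated as fixed (the NOME
  assumption behind the standard GLS-IVW). With a small exposure GWAS and a
  non-null effect this is visibly optimistic: at n\_exposure = 5,000 versus
  n\_outcome = 100,000 and $\alpha = -0.2$, exposure-beta noise adds roughly
  $(\alpha\,\sigma_X/\sigma_Y)^2 \approx 40\%$ (plus interaction terms) to
  the true slope variance, so the nominal 95% CI covers ~80% in our
  simulations and the slope is diluted towards the null by
  $\approx J/(n_{\mathrm{exp}}\,h^2_{\mathrm{marginal}})$ (~0.6% here). Both
  distortions vanish as the exposure GWAS grows (coverage is 0.950 at
  n\_exposure = 100,000 with the same code) and the dilution acts towards a
  neutral — conservative — direction, which is also the argument the
  two-sample design itself relies on. Users with small exposure GWASs
  should read the CI as approximate and the F ≥ 24 filter as load-bearing.
* The Q-difference selection level, palindrome policy and prune-then-select
  ordering are conventions, configurable but not data-derived.
* Binary-outcome effects are non-collapsible marginal log-odds; comparing
  them to a conditional generating model shows small systematic
  attenuation.
* The LD shrinkage ladder caps at $\lambda = 0.05$; panels so degenerate
  that this fails raise an error rather than a silent fix.

## Reproducing the numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes the
analytic thresholds, the end-to-end pipeline slope on a simulated study, the
Monte-Carlo recovery/coverage/type-I/pleiotropy rates (at reduced replicate
counts), and the stratified-interaction p-value from the published
carrier/non-carrier odds ratios. The full-size experiments live in
`tests/testthat/test-acceptance.R`.
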