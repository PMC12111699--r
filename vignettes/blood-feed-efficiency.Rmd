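---
title: "Associating hematology and whole-blood gene expression with feed-efficiency traits"
author: "bloodFE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associating hematology and whole-blood gene expression with feed-efficiency traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodFE)
```

# The problem

Feed is the dominant cost of raising beef heifers, and feed efficiency —
how an animal converts feed into body-weight gain — is the trait producers
most want to improve.  Whole blood is the one tissue that can be sampled
from every animal in a trial without biopsy, so a natural question is
whether hematology profiles and whole-blood gene expression carry signal
about the continuous feed-efficiency phenotypes: average daily gain (ADG,
kg/d), average daily feed intake (ADFI, kg/d) and their ratio, gain-to-feed
(G:F).

Blood is also the tissue where the statistical pitfalls are sharpest.  A
bulk RNA-seq profile of whole blood is an average over neutrophils,
lymphocytes, monocytes, eosinophils, basophils and erythrocyte-lineage
cells, and animals differ substantially in those proportions.  Any gene
whose expression marks a cell type will appear trait-associated whenever
cell composition itself tracks the trait.  This package implements, as a
tested and reusable pipeline, a quantitative analysis built around that
problem:

1. **Trait derivation** — ADG from a quadratic regression of serial body
   weights on day of study; G:F = ADG/ADFI per animal.
2. **Hematology scan** — per-parameter linear mixed models of the 15
   complete-blood-count (CBC) parameters against each trait, with
   baseline-R² accounting.
3. **Count preprocessing** — low-expression filtering, median-of-ratios
   normalization, log transform, variance-filtered PCA, and a 98.5%
   confidence-ellipse sample outlier screen.
4. **Differential expression for a continuous trait** — both the trait and
   every gene's expression are residualized on the same confounder design
   (herd factors plus blood cell-type proportions) with a mixed model, the
   residuals are correlated gene by gene, and discoveries are controlled by
   Benjamini–Hochberg FDR at 0.1.

Every stage runs against a synthetic-herd generator with known ground
truth, so all operating characteristics claimed here are recomputed by the
test suite and the acceptance script, not asserted.

# The mixed model

All association steps share one statistical core, fitted by REML:

$$y = X\beta + Zu + e,\qquad u \sim N(0,\sigma_s^2 I_q),\qquad
  e \sim N(0,\sigma_e^2 I_n),$$

where $X$ holds an intercept, dummy-coded breed and pen, and numeric
covariates (age, a CBC parameter, or the six cell-type covariates), and
$Z$ is the one-hot indicator of sire, the single random effect.  Because
$Z^\top Z$ is diagonal for a grouping factor, the marginal covariance
$V = \sigma_e^2 (I + \lambda ZZ^\top)$ with $\lambda = \sigma_s^2/\sigma_e^2$
admits closed-form Woodbury inversion, and the whole REML profile reduces
to summary statistics ($X^\top X$, $Z^\top X$, $Z^\top y$, group sizes) —
$O(qp^2)$ per evaluation regardless of $n$.  $\sigma_e^2$ is profiled out
analytically and $\lambda$ is maximized over $[0,\infty)$ by a 61-point
log grid on $[10^{-6},10^3]$ plus golden-section refinement (absolute
tolerance $10^{-8}$ on $\lambda$), with the $\lambda = 0$ boundary
evaluated exactly: there the fit *is* ordinary least squares, and the
tests assert that reduction to $10^{-8}$ relative precision.

Design matrices are rank-checked by singular value decomposition before
fitting; aliased columns are dropped and recorded rather than silently
absorbed, mirroring the dependency check a careful analyst performs before
a mixed-model scan.  Wald p-values use $t = \hat\beta/\mathrm{SE}$ with
$n - \mathrm{rank}(X)$ denominator degrees of freedom — a deliberate,
documented approximation (no Satterthwaite correction); a 1000-replicate
null simulation in the test suite confirms its type-I error sits in
$[0.03, 0.07]$ at the 0.05 level for herds of this size.

"Model R²" has no unique mixed-model definition, so the package commits to
one and exposes both variants: the default conditional R² is the squared
correlation between observations and $X\hat\beta + Z\hat u$ (credits the
sire predictions), and marginal R² uses $X\hat\beta$ only.  The hematology
scan reports each parameter's conditional R² and its increment over a
design-only baseline model (breed + pen + age + sire), computed once per
trait and cached.

# The differential-expression procedure

Counts are filtered (a gene is removed when its mean count is below 10
*or* it is zero in more than 80% of samples — the OR reading is the
conservative one; per-criterion removal counts are logged and an AND
variant is exposed), normalized by median-of-ratios size factors,
transformed as $\log_2(\text{count}/\text{factor}+1)$, and screened for
outlying samples: the lowest 10% of genes by variance are dropped, samples
are projected onto the first two principal components, and any sample
whose squared Mahalanobis distance in that plane exceeds the
$\chi^2_2$ quantile at 0.985 is removed.  The $\chi^2$ ellipse was chosen
over a $t$-ellipse because it is closed-form and parameter-free; a
10,000-point bivariate-normal simulation in the tests confirms the flag
rate lands in $[0.010, 0.020]$ around the nominal 0.015.

For each trait, both the trait and every retained gene's log expression
are then adjusted with the *same* mixed model: breed and pen fixed, sire
random, age plus six cell-type covariates — the five leukocyte counts as
fractions of WBC, and the red-cell count as its absolute concentration
(a proportion of WBC would be meaningless for erythrocytes).  Conditional
residuals $y - X\hat\beta - Z\hat u$ are the adjusted values (marginal
residuals would leave sire structure in both vectors and recorrelate
them).  The per-gene association statistic is the Pearson correlation of
the two residual vectors, reported as `reg` on the correlation scale.

## Degrees of freedom: a correction the data forced

The naive convention treats the residual correlation as an ordinary
correlation on $n$ samples ($t$ on $n-2$ df).  That convention is
internally consistent with the genome-scale worked example the tests
reproduce (r = 0.5763 with 57 df gives p = 1.78e-6), but it is wrong for
the pipeline's own inference: residualizing on a rank-13 fixed design
confines both vectors to an $(n-13)$-dimensional subspace, and the null
variance of the correlation is $1/(n-1-\mathrm{rank}(X))$, not $1/(n-2)$.
We measured exactly that on synthetic nulls (variance 0.0223 over 20 seeds
at $n = 59$, against $1/45 = 0.0222$), and the far tail was inflated four-
to five-fold — enough to break FDR control outright (9 of 20 null runs
produced discoveries).  The package therefore defaults to the classic
partial-correlation df, $n - 2 - k$ with $k$ the number of absorbed
non-intercept columns, which is identical to $n-2$ when nothing is
absorbed; the uncorrected convention remains available as
`dfMethod = "classic"` for comparability with analyses that used it.

Nominal p-values are adjusted by the Benjamini–Hochberg step-up rule with
the total test count $m$ equal to the number of genes actually tested
(15,315-scale after filtering at full size; an `mTotal` override supports
adjusting a printed subset against a larger count), and genes with
adjusted p below 0.1 are flagged.

# The synthetic-herd generator

The generator is first-class, tested code; its defaults *are* the study
conditions everything else is validated under: 61 heifers of 3 breeds from
12 artificial-insemination sires in 4 pens; a 34,000-gene count matrix of
which roughly 45% survive the low-expression filter (emulating 15,315 of
33,845); and two planted expression-outlier samples so the default study
retains 59 after the ellipse screen.

**CBC panel.** The five leukocyte differential counts are independent
log-normals moment-matched to the herd anchor means/SDs, and WBC is their
exact sum.  The erythrocyte series is a trivariate log-normal on (RBC,
MCV, MCHC) whose log-scale correlations are solved in closed form so the
derived instrument identities HCT = RBC·MCV/10, HGB = MCHC·HCT/100 and
MCH = MCHC·MCV/100 reproduce the anchor means — the anchor set is mutually
inconsistent under independence, and the implied negative RBC–MCV
correlation (about −0.67 on the log scale) is also the biologically
expected one.  When every anchor SD is zero the panel degenerates to the
anchor means themselves, a noise-free pinning mode used by tests; the
instrument identities then hold only to the anchors' printed precision.

**Traits and growth.** Latent ADG and ADFI are anchor mean plus centered
breed/pen effects, an age slope, linear CBC effects (the estimand of the
hematology scan), a sire effect with the configured variance, and a
residual sized so the total variance matches the anchor SD²;
G:F = ADG/ADFI per animal, exactly.  Because G:F is a literal ratio its
expectation carries the second-order bias $\mu_A/\mu_F(1+\mathrm{cv}_F^2)$
(about −0.0006 against the 0.11 anchor), which the moment tests allow for
explicitly.  Body weights follow a quadratic curve whose curvature comes
from a quadratic fit of the population weight anchors and whose linear
term is set per animal so the fitted day-84 gain equals 84·ADG; weigh
days are 0, 1, 21, 42, 63, 84 with 3 kg scale noise.

**Counts.** $\log \mu_{gs} = \text{baseline}_g + \log f_s + c\,w_g^\top
z_s + \delta_g \tilde t_s$, with library factors $f_s$ log-normal
(SD 0.15), a unit-direction cell-composition term on 30% of genes at
strength 0.3, and, for planted genes, a trait term along the
design-and-composition-residualized standardized trait $\tilde t$.  The
effect size is calibrated as $\delta_g = \pm r/\sqrt{1-r^2}\cdot
\sqrt{1/\mu_g + \phi}$ so that the *post-adjustment* partial correlation
targets the configured $r$ (planted genes are kept well-expressed, mean
count ≈ 300, so the delta-method noise approximation holds).  Sampling is
negative binomial with dispersion $\phi = 0.05$ (variance
$\mu + \phi\mu^2$), reducing exactly to Poisson at $\phi = 0$.  Outlier
samples receive an independent per-gene log-normal shift (SD 1.0), which
displaces them violently in PC space without moving their median-of-ratios
size factor.

One master seed drives everything; each stage draws from its own derived
child seed, so stages are reproducible independently and a rerun is
byte-identical.

## What the generator does not emulate

Real whole-blood data have correlated CBC parameters beyond the
instrument identities, gene–gene correlation networks, batch structure,
globin-transcript inflation, and cell-composition effects that are neither
linear nor fully captured by six covariates.  Passing tests on this
generator therefore demonstrate that the *procedure* is correctly
implemented and calibrated under its own assumptions — linear confounding,
NB counts, a single random effect — not that those assumptions hold in any
particular herd.

# Worked example

```{r example, eval = FALSE}
se <- simulateStudy(simConfig(seed = 1))
prep <- prepCounts(se)
prep
de <- runDE(prep, trait = "GF", meta = se, cbc = se)
head(de)
```

# Numerical choices and problem sizes

* $\lambda$ grid $10^{-6}\ldots10^3$ (61 points) + golden section,
  tolerance $10^{-8}$; non-convergence returns the best grid point with
  `converged = FALSE`.
* Rank tolerance: singular values below
  $\max(n,p)\cdot\epsilon\cdot d_1$; dropped columns recorded.
* PCA sign convention: each component's largest-magnitude gene loading is
  made positive, so score signs are reproducible across BLAS builds.
* Degenerate genes (zero residual variance) are reported with r = NA,
  p = 1 and a flag rather than dropped, keeping the BH test count honest.
* The test suite exercises the study scale directly: null-FDR and power
  simulations use 20 seeds × 2,000 genes at 61 animals (59 retained),
  variance-component recovery uses 20 seeds at n = 2,000 with 100 sires,
  and the brute-force REML grid oracle runs at n = 40.  These sizes give
  each stochastic check a comfortable margin at its stated tolerance while
  keeping a full run in the minutes range.

# Known limitations

* One random effect only — no crossed or nested terms, no GLMMs, no
  Satterthwaite/Kenward–Roger df.
* The Wald df and the partial-correlation df are both finite-sample
  approximations; they are validated by simulation at herd sizes near the
  default, not asymptotically.
* The ellipse screen is limited to two components by design.
* No shrinkage estimation, variance-stabilizing transforms, batch
  correction, or enrichment analysis.
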