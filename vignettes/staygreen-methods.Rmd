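---
title: "Models and methods: senescence kinetics, split-plot REML and G x T GWAS"
author: "staygreenGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: senescence kinetics, split-plot REML and G x T GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The logistic senescence model

Flag-leaf chlorophyll content (CHL, ug cm^-3^) after anthesis is modelled
per plant as

$$\mathrm{CHL}(t) = D + \frac{K}{1 + a\,e^{rt}},$$

with $t$ thermal time after anthesis in degree-days (°Cd).  $D$ (ug cm^-3^)
is the residual CHL of the dead leaf, $K$ (ug cm^-3^) the amplitude of the
decline, $r$ (per °Cd) the rate parameter and $a$ (dimensionless,
$0 < a < 1$ for declines whose onset is after anthesis) the timing
parameter.  The model assumes a single, complete, sigmoidal decline; it
cannot represent transient re-greening or bimodal kinetics.

**Pseudo point.**  Measurement usually stops before the leaf is fully
dead, which leaves the lower asymptote unidentified.  `addPseudoPoint()`
appends one observation 200 °Cd after the last measurement at the CHL of a
fully senesced leaf.  The dead-leaf constant is a tuning parameter
(`deadChl`, default 5 ug cm^-3^, the panel-level mean of $D$); it is
exposed because no canonical value exists.

**Two-pass fitting.**  `fitLogistic()` minimises the residual sum of
squares over $(D, K, \log a, r)$ with Levenberg–Marquardt
(`minpack.lm::nls.lm`), bounded by $K > 0$, $r > 0$.  Optimising
$\log a$ rather than $a$ is essential: typical values of $a$ are
$10^{-7}$–$10^{-4}$ and a linear-scale step would be degenerate.  Starting
values come from the curve's own geometry ($D_0 = \min$ CHL,
$K_0 = $ range, $\mathrm{XPI}_0 = t$ at half decline,
$r_0 = 4|\text{steepest slope}|/K_0$, $\log a_0 = -r_0\,\mathrm{XPI}_0$);
because a single noisy dip can fool the closest-to-half rule, two
alternative onset candidates (first half-crossing, schedule median) are
tried and the best deviance kept.  Pass 1 fits all points; outliers are
flagged on the pass-1 residuals; pass 2 refits without them (at most 30%
of points may be dropped).  Optimiser failure is reported as
`converged = FALSE`, never as an error — a few percent of real curves
cannot be fitted, and a batch run must survive them.

**Outlier rule.**  `detectOutliers()` re-implements a quantile-based
normal-tail rule: a normal distribution is fitted by least squares to the
sorted residuals against normal quantiles inside the central window
(default 25th–75th percentile), and an observation is flagged when the
expected number of observations at least as extreme under that normal
falls below `rho` (default 0.5).  `rho` is read as the *total* expected
false count, split across the two tails (each tail limit is the
$\rho/2n$ quantile); the one-sided reading flags visibly more clean
points.  Both the window and `rho` are exposed.

**Traits.**  With $u(t) = a e^{rt}$, the inflection is at $u = 1$, giving
$\mathrm{XPI} = |\ln a|/r$, $\mathrm{YPI} = K/2$ (half-amplitude; the CHL
*level* at the inflection is $D + K/2$) and
$\mathrm{VIT} = f'(\mathrm{XPI}) = -Kr/4$.  Onset and completion are
defined at the extrema of the third derivative, $u = 5 \mp 2\sqrt 6$:

$$\mathrm{START} = \frac{\ln(5 - 2\sqrt6) - \ln a}{r},\qquad
  \mathrm{END} = \frac{\ln(5 + 2\sqrt6) - \ln a}{r}.$$

Because $(5-2\sqrt6)(5+2\sqrt6) = 1$, these are exactly symmetric about
XPI, and $f_\mathrm{START} + f_\mathrm{END} = 2D + K$.  An alternative
convention places onset/completion at the extrema of the *second*
derivative ($u = 2 \mp \sqrt3$); it yields a narrower window and is
available via `deriveTraits(rule = "second-derivative")`.  The
third-derivative rule is the default because only it reproduces the
panel-mean CHL values at onset (~47 ug cm^-3^) and completion
(~9.3 ug cm^-3^) implied by the panel means of $D$ and $K$ — the
acceptance suite computes this check.

**Areas.**  Using the antiderivative
$\int (f - D)\,dt = K\left[t - \ln(1 + a e^{rt})/r\right]$, `AUCK`
integrates $f - D$ from anthesis to END and `AUC` from START to END
(`aucFrom = "anthesis"` switches AUC to the anthesis origin).  The
integration origin and whether the $D$ baseline is included are the one
place where published panel summaries and the geometric description of
the shaded "area under the senescence curve" cannot be reconciled
exactly; the choice here is the literal reading of the closed forms, and
it is config-exposed rather than silent.

**Batch quality rules.**  `fitSenescence()` replaces manual curve
curation with automated flags: END more than 400 °Cd beyond the last
observation, $D \notin [-5, 20]$ ug cm^-3^, or pseudo-R^2^ < 0.7 mark a
plant as `qcFlag = TRUE`.  Degenerate parameter escapes (e.g. $a$
underflowing to 0 when no decline falls inside the window) yield `NA`
traits and a flag instead of an error.

## 2. The synthetic-data generator

The generator exists so that every downstream stage can be tested against
known truth.  Its defaults *are* the study conditions: ~199 genotypes, 21
chromosomes, two treatments (NS/S), three replicates, five sub-blocks per
whole plot, two years.

**Genotypes** (`simulateGenotypes()`).  Inbred lines: one founder
haplotype per genotype and block, so true dosages are 0/2; heterozygous
calls (default 1%) are injected as the genotyping-error process that QC
later recodes to missing, and missing calls (default 8%) are uniform and
independent of dosage.  LD comes from a block-haplotype scheme: SNPs are
partitioned into blocks with geometric lengths (mean `ldBlockMeanSnps`,
default 5); each block has two founder haplotypes at a random frequency,
and each SNP couples to the founder indicator with the maximal correlation
compatible with its own target MAF (drawn from `mafRange`, default
0.05–0.5).  Within-block r^2^ is therefore high, between-block r^2^ is at
the independence level, and `ldBlockMeanSnps = 1` gives fully independent
SNPs.  This is deliberately simpler than coalescent simulation: it gives
the pruning, kinship, threshold and interval code the LD geometry they
need, but no realistic demography, no LD decay *within* a block, no
selection and no real genetic map.

**Phenotypes** (`simulatePhenotypes()`).  One record per genotype x year
x treatment x replicate, with genotypes allocated to sub-blocks by a
seeded shuffle within each whole plot.  The value is the sum of the
general mean, fixed year and stress effects, an i.i.d. sub-block effect,
a polygenic effect with covariance $\sigma^2_g K$, genotype-by-treatment
and genotype-by-year deviations drawn independently per treatment/year
with covariance $\sigma^2_{gt} K$ and $\sigma^2_{gy} K$ (the equivalent
of the Hadamard $K \circ I$ structure), planted QTL contributions
(dosage x (main + interaction x 1[S])), and i.i.d. residual.  Defaults
are thousand-kernel-weight-like: variance components
12.3 / 4.24 / 4.39 / 32.2, a fixed stress loss of 10.5 on a non-stress
mean of 44.4 (~24%), and year effects ±2.4.  A method-of-moments ANOVA
check in the test suite verifies that the generated data reproduce these
components.

**Senescence curves** (`simulateSenescenceCurves()`).  Per plant, true
parameters are drawn around panel-scale means: $D \sim N(5.1, 1.0)$,
$K \sim N(46.1, 3.2)$ truncated positive, $r \sim N(0.0228, 0.0022)$
truncated positive, and $\log a \sim N(-14.42, 0.9)$ — $a$ log-normal,
matching the observation that all parameters but $a$ look normal.  The
log-mean is back-derived so that the mean onset sits near 532 °Cd; the
between-plant spreads are *synthetic defaults*, because between-genotype
variances of the senescence parameters are not published.  Stress shifts
the onset 28 °Cd earlier via $a \mapsto a\,e^{r\Delta}$, which translates
the whole curve and leaves its shape unchanged (panel onset stress index
~5%).  Observations sit on a regular thermal-time schedule — default 19
measurements every 50 °Cd, i.e. roughly two CHL readings a week over
grain filling — plus Gaussian noise and random-sign outliers (5% at
15 ug cm^-3^).  The noise default (3.8 ug cm^-3^) was calibrated once so
that the mean fitted pseudo-R^2^ lands in the 0.94–0.98 band of the real
experiments, and then frozen.  What passing tests on these curves show is
that the estimator recovers the truth *under the model plus noise and
outliers*; they cannot show robustness to model misspecification
(re-greening, drought co-stress, sensor drift), which real data may
contain.

**Seeding.**  Every generator consumes one seeded stream per logical
component (genotypes, effects, curve noise), derived from the user seed;
identical seeds reproduce outputs bit-identically, and changing one spec
does not perturb the draws of another.

## 3. Split-plot REML with kinship

`fitSplitPlot()` fits, for a single year,

$$Y_{ijkl} = \mu + R_j + T_k + (T\!\times\!R)_{jk} + B_{l(jk)} + G_i +
             (G\!\times\!T)_{ik} + \varepsilon_{ijkl},$$

with fixed replicate/treatment structure and random
$B \sim N(0, \sigma^2_l)$, $G \sim N(0, \sigma^2_g K)$,
$(G\times T) \sim N(0, \sigma^2_{gt}\, K \circ I_T)$,
$\varepsilon \sim N(0, \sigma^2_\varepsilon)$.  The multi-year model adds
fixed year, year-by-treatment and replicate-within-year terms and a
$K \circ I$ genotype-by-year effect.  Part of the three-way
$G \times T \times Y$ interaction is then confounded with the residual;
this is a property of the design and is reproduced, not "fixed", so
$\sigma^2_{gt}$ and $\sigma^2_{gy}$ are to be read as lower bounds in the
multi-year fit.  The $K \circ I$ structure is implemented as independent
$K$-covariant vectors per treatment (algebraically identical, cheaper).

**REML engine.**  The variance components are estimated by
average-information (AI) REML on the observation-level covariance
$V = \sum_i \theta_i M_i + \theta_\varepsilon I$ with dense kernels
$M_i = Z_i K_i Z_i'$: per iteration one Cholesky factorisation and one
inverse of $V$, the REML gradient, and an AI (Fisher-scoring-like) step
with step-halving; when the AI step fails to increase the restricted
likelihood an EM step (guaranteed ascent) is taken instead.  Components
are floored at $10^{-8}\,\mathrm{var}(y)$ — boundary estimates are
reported as (numerical) zero, never negative.  Convergence requires a
relative restricted-log-likelihood change below `tolLl` (default 1e-9)
together with a scaled-gradient check; the likelihood trace is kept and
tested to be monotone.  Aliased fixed-effect columns are dropped by
pivoted QR.  On balanced identity-kinship designs the solution matches
closed-form expected-mean-square estimators to 1e-6 (an acceptance
check), and it matches `lme4` on the same model in the unit tests; the
engine exists in-package because no installed package fits a dense
kinship covariance with the $K \circ I$ interaction structure.

**Derived quantities.**  `heritability()` implements
$H^2 = \sigma^2_g \big/ \big(\sigma^2_g + \sigma^2_{gt}/t +
\sigma^2_{gy}/a + \sigma^2_\varepsilon/(atn)\big)$ (single-year: drop the
year term).  `gblupByTreatment()` returns
$\mathrm{GGT}_{ik} = \hat\mu_k + \hat G_i + \widehat{(G\times T)}_{ik}$,
where $\hat\mu_k$ is the estimated fixed-part mean of treatment $k$ —
including the treatment effect in $\hat\mu_k$ is what lets the stress
index read the fixed stress impact off the gBLUP table.
`stressIndex()` is $100(\overline{\mathrm{GGT}}_{NS} -
\overline{\mathrm{GGT}}_S)/\overline{\mathrm{GGT}}_{NS}$: the published
subscript labelling of the two treatments is internally inconsistent, and
the orientation here (positive = loss under stress) is fixed by the sign
convention of the published stress indices.  `lrtRandom()` uses the
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ boundary mixture by default (a
variance tested on the edge of its space), with a plain $\chi^2_1$
switch; at a zero statistic the mixture p-value is 0.5.

## 4. The association scan

`runScan()` adds, per SNP, two fixed effects to the split-plot model:
allelic dosage $x$ and $x \times 1[S]$.  The main estimate is therefore
the allelic effect in the non-stress treatment and the sum of the two is
the effect under stress (reported as `effectS`).  Both terms get 1-df
Wald chi-square tests; p-values are floored at 1e-300 (LOD capped at
300).  To avoid proximal contamination, each SNP is tested with a kinship
matrix computed from all chromosomes except its own; by default the
kinship panel is first LD-pruned (tree cut at distance 0.1), as was done
for the relationship matrix of the study.

**P3D vs full refit.**  In the default P3D mode the variance components
are estimated once per chromosome under the no-SNP model and held fixed;
each SNP is then a generalised-least-squares problem solved by whitening
(one triangular solve for all SNPs of a chromosome) and
Frisch–Waugh residualisation, with coefficient covariance
$(X^{*\prime} V^{-1} X^*)^{-1}$ — no residual rescaling, since the
components live in $V$.  `mode = "full"` re-estimates the components per
SNP (the published analysis refit the complete model); a unit test pins
the rank agreement of the two modes.  Monomorphic or
collinear SNPs are reported with `NA` statistics and a reason, never
dropped silently.

**Threshold.**  `gaoThreshold()` eigendecomposes each chromosome's SNP
correlation matrix; $M_{\mathrm{eff},c}$ is the smallest number of
leading eigenvalues reaching 99.5% of the total, and the genome-wide
threshold is $-\log_{10}(\alpha/\sum_c M_{\mathrm{eff},c})$.  The cited
effective-test-count method has two variants differing in the eigenvalue
fraction; 0.995 is the common default and the fraction is exposed.  The
published threshold value (5.26) belongs to the original 164,198-SNP
array panel and is not reproducible without it; the acceptance suite
instead pins the analytic limits (fully redundant panel:
$-\log_{10}\alpha$; independent panel: the Bonferroni value).

**Interaction variance explained.**
`interactionVarianceExplained()` is the R^2^ of the simple regression of
genotype-by-treatment coefficients on fitted SNP-by-treatment effects.
Two subtleties, documented because they change the number: the G x T
BLUPs must come from the *no-SNP* baseline model (in the SNP-including
model the SNP's share has been removed from the BLUPs), and a dosage x
indicator term contains a genotype-main component, so only half of its
raw variance lives in the identifiable interaction space.  The test suite
plants a SNP carrying ~15% of the identifiable interaction variance and
regresses the per-genotype stress-response contrast of the BLUPs on the
SNP term.

## 5. QTL delimitation

`clusterSignificantSnps()` groups the significant SNPs of a chromosome by
average-linkage clustering on $1 - r^2$, cutting the tree at one
"critical LD unit".  The phrase admits two readings: cut height
$1 - 0.24 = 0.76$ (SNPs in a cluster share average r^2^ above the
critical level — the default) or cut height 0.24; both are exposed
(`cutAt`).  `ldDecay()` fits the Hill–Weir drift expectation of r^2^
(with finite-sample term) to pairwise r^2^ versus distance by least
squares over a 10 Mb window centred on the cluster, and returns the
distance at which the expected r^2^ crosses the critical level; windows
with fewer than 20 pairs fall back to the whole chromosome (flagged), and
a degenerate fit falls back to empirical binned medians.  A panel with no
LD anywhere yields a decay of zero.  `qtlBoundaries()` extends the member
span by the decay distance on each side, clipped to the chromosome, and
records the lead SNP (maximal LOD).  The published description of the
decay estimator ("specific to the genomic area") is not detailed enough
to pin one estimator; both the model-based and the empirical route are
provided and the choice is logged in the result's attributes.

## 6. Numerical choices and degenerate inputs

* Logistic fitting: LM tolerances 1e-14 (ftol) / 1e-12 (ptol), 300
  iterations, three starts; constant curves and sub-5-point curves are
  rejected up front; `a` underflow is flagged downstream, not fatal.
* REML: AI step with up to 9 halvings, EM fallback, floor
  $10^{-8}\mathrm{var}(y)$; warm starts (previous chromosome/seed) cut
  iteration counts roughly in half and change nothing at convergence.
* Pruning and clustering: SNPs are processed in map order, so results do
  not depend on input column order; the representative SNP of a pruning
  cluster is a seeded uniform draw (the published method says "randomly
  selected" without a rule).
* LD decay: the rate parameter is searched on a log grid over
  $e^{-25}$–$e^{8}$ per bp; crossings below 1 bp are reported as 0.
* Wald p-values are floored at 1e-300; zero-variance regressors raise
  explicit undefined-result errors rather than returning NaN.

## 7. Problem sizes used by the checks

The test suite and acceptance script run entirely on synthetic data at
sizes chosen to exercise the study geometry while staying desk-scale:
trait-oracle agreement on 1000 random parameter sets; logistic recovery
on ~500 curves; variance-component recovery at the full 199-genotype,
two-year design over 20 seeds; GWAS calibration on 2,000 SNP tests (200
genotypes, 10 chromosomes); interaction-QTL detection over 20 seeds at
200 genotypes x 2,000 SNPs.  The published headline numbers that depend
on the real (undeposited) phenotype and genotype data — the exact stress
indices, the 5.26 threshold, the 17 QTL — are covered by these
property-based surrogates, not reproduced.

## 8. Known limitations

* The senescence generator cannot produce curves outside the logistic
  family, so fit-quality results do not certify behaviour on
  non-sigmoidal kinetics.
* The block-LD scheme has constant LD within a block and none between;
  LD-decay estimates on it test the machinery, not wheat-like decay
  rates.
* The REML engine is dense ($O(n^3)$ per iteration) and is comfortable
  to a few thousand plants; field-scale multi-environment sets would need
  sparse or eigendecomposition-based algebra.
* Under a boundary-true null (no genetic variance at all) the estimated
  positive variance components make the SNP main-effect Wald test mildly
  conservative in small single-year designs; the calibration check
  therefore runs on the two-year design, where the effect vanishes.
* Phasing-based imputation is out of scope; binomial frequency
  imputation is a stand-in that is adequate for kinship and single-SNP
  tests but not for haplotype analyses.
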