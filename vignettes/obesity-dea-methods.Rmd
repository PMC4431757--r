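---
title: "Efficiency scores, genetic risk, and obesity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficiency scores, genetic risk, and obesity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obesityDEA)
```

## The question the package answers

Two people with the same body-mass index can be heavy for very different
reasons: one eats a lot and rarely exercises, the other lives carefully and
is heavy anyway.  The first person's obesity is environmentally driven and
is the natural target of diet-and-exercise interventions; the second
person's weight is largely set by factors — genetic and otherwise — that
lifestyle advice will not move.  This package separates the two by scoring
every cohort subject with data envelopment analysis (DEA) and comparing
that score, in regression models of BMI, against a conventional weighted
genetic predisposition score (GPS).

## The efficiency score

Each subject is a decision-making unit (DMU) converting two inputs —
physical-activity energy expenditure (METs-h/day) and the *inverse* of
caloric intake (day/kcal) — into one output, the *inverse* of BMI
(m²/kg).  Inverting intake and BMI makes "eat less" and "weigh less" point
in the improving direction for an input-oriented model.  The
input-oriented, constant returns-to-scale (Charnes–Cooper–Rhodes)
envelopment program for target DMU $o$ is

$$\min_{\theta,\lambda}\ \theta
\quad\text{s.t.}\quad
\sum_j \lambda_j x_{ij} \le \theta\, x_{io}\ (i=1,2),\qquad
\sum_j \lambda_j y_{j} \ge y_{o},\qquad \lambda \ge 0 .$$

$\theta^\ast \in (0,1]$ is the efficiency score: 1 means the subject lies
on the empirical frontier (no convex combination of peers produces at least
the same output from radially smaller inputs); the reference set is the
peers with $\lambda_j$ above $10^{-7}$.  Because the target always envelops
itself ($\lambda_o = 1$), the program is feasible for any strictly positive
data.  One LP is solved per subject with the simplex routine from the
**boot** package.

The multiplier (dual) form — maximise $u^\top y_o$ subject to
$v^\top x_o = 1$ and $u^\top y_j \le v^\top x_j$ for all $j$ — is also
implemented (`solve_ccr_multiplier()`).  It is used as a strong-duality
oracle in the test suite rather than for production scoring: duality
equality within $10^{-6}$ is checked on 100 random instances per run, and
for single-input/single-output data both forms are verified against the
closed form $\theta_j = (y_j/x_j) / \max_k (y_k/x_k)$.

### Numerical choices

* **Conditioning.**  The two inputs differ by five orders of magnitude
  (about 36 METs-h/day versus about $4.4\times10^{-4}$ day/kcal).  CCR
  scores are invariant to per-column rescaling, so every input/output
  column is internally normalised to unit mean before the LP is solved
  (`solver_options(rescale = )`, on by default); scores are returned on
  the original data.
* **Tolerances.**  Simplex feasibility tolerance $10^{-9}$; envelopment
  constraints re-checked at the reported optimum; scores within $10^{-6}$
  of 1 are reported as exactly efficient, and reported scores are clipped
  to $[10^{-12}, 1]$ while the raw optimum is kept in `theta_raw`.
* **Radial scores only.**  The second-stage slack-maximisation refinement
  of the CCR model is not implemented: only $\theta$ is contractual.  The
  optimal $\lambda$ may be non-unique and is reported as information only.
* **Degenerate input.**  A one-DMU set returns $\theta = 1$ without
  invoking a solver.

## The genetic predisposition score

For $L$ loci with effect-allele dosages $a_l \in [0,2]$ (fractional after
imputation) and GWAS effect sizes $\beta_l > 0$:

$$\mathrm{GPS} \;=\; \frac{\sum_l a_l\beta_l}{2\sum_l \beta_l}\times 2L
\;=\; L\,\frac{\sum_l a_l\beta_l}{\sum_l \beta_l}\ \in\ [0,\,2L],$$

the standard weighted risk-score rescaling that puts the weighted sum back
on the allele-count scale: 0 means no effect alleles anywhere, $2L$ means
homozygous for the effect allele at all $L$ loci, and with equal weights
the score reduces to the plain allele count.  The reference configuration
is $L = 29$, so scores live in $[0, 58]$.  Before scoring, SNPs with minor
allele frequency below 0.5% or call rate below 95% are removed
(`qc_filter_snps()`); these filters are applied to whatever dosage matrix
is supplied, whether genotyped or imputed.  Missing dosages are handled by
per-subject renormalisation over the observed loci (keeping the $[0,2L]$
scale), with `missing = "fail"` available for strict pipelines.  Dosages
can be read from a wide CSV or from a VCF (GT, with DS honoured when
present); when the effect allele is the REF allele the ALT count is
flipped.

## The regression models

Five specifications are fitted with BMI at baseline — or the yearly BMI
change over a 5–7-year follow-up — as the dependent variable, all adjusted
for age and sex (women coded 1, men 0):

| Model | Covariates beyond age + sex |
|-------|------------------------------|
| M1 | expenditure, intake |
| M2 | efficiency score |
| M3 | GPS |
| M4 | expenditure, intake, GPS |
| M5 | GPS, efficiency score |

The change analysis first restricts to subjects with a *baseline* BMI in
the normal range (18.5 to <25 kg/m²; the 18.5/25 cut-points are half-open,
so 18.5 is normal and 25.0 is overweight) and available follow-up.  The
exclusion uses baseline BMI because that is the only measure available at
cohort entry, matching the study-flow ordering.

The production estimator is an MM-type robust regression (bisquare
$\psi$, 95% asymptotic efficiency, high-breakdown resampling start) as
provided by `MASS::rlm(method = "MM")`; coefficients are reported with
their asymptotic robust standard errors and normal-approximation p-values,
without multiple-testing correction.  The reported $R^2$ in MM mode is the
coefficient of determination computed with the final IRWLS weights and the
classical $(n-1)/(n-p-1)$ adjustment — a documented convention, since
robust fits admit several $R^2$ definitions.  `method = "ols"` switches to
ordinary least squares and serves as the oracle mode in tests (exact
agreement with the normal-equations solution, classical adjusted $R^2$,
and the nesting property that adding a covariate cannot lower in-sample
$R^2$).  If the data are fitted exactly (zero residual scale) the MM loss
is undefined and the least-squares interpolant is returned, which is the
unique robust solution in that degenerate case.  Rows with missing values
are dropped listwise, so the per-model `n` is reported with every fit.

## The synthetic cohort generator

No subject-level data from the motivating cohort are distributable, so the
package ships a generator (`sim_config()`, `simulate_cohort()`,
`simulate_followup()`) whose defaults reproduce that study's published
marginal structure: ages 40–84, 726:894 men:women, intake
$\mathcal N(2257, 673^2)$ kcal/day truncated below 300, expenditure
$\mathcal N(36.2, 5.8^2)$ METs-h/day truncated below 20, genotypes drawn
per locus as Binomial(2, $f_l$) under Hardy–Weinberg equilibrium, and
baseline BMI from the additive structural model

$$BMI_i = b_0 + b_{sex}\,\mathbb 1[\text{woman}_i] + b_{age}\,age_i +
\gamma\,GPS_i + \delta_{int}\,intake_i + \delta_{exp}\,expend_i +
\varepsilon_i,\qquad \varepsilon_i \sim \mathcal N(0, \sigma^2),$$

truncated to the observed range $[15, 36]$ kg/m² by resampling the noise
term.  Defaults: $b_0 = 19.2$, $b_{sex} = -0.4$, $b_{age} = 0.02$ per
year, $\gamma = 0.06$ per GPS unit, $\delta_{int} = 0.002$ per kcal/day,
$\delta_{exp} = -0.08$ per METs-h/day, $\sigma = 2.6$; together they put
the simulated BMI mean and SD at the published 23.4 (3.1).  Only marginal
moments are published, so the joint generative model — additive linear
BMI, independent environment variables, HWE genotypes, no LD — is this
package's choice; it is exactly the structure the regression models
assume.  Effect-allele frequencies default to $U(0.2, 0.7)$ (the
BMI-raising allele need not be the minor allele) and weights to
$U(0.05, 0.35)$, which centres the 29-locus GPS near the published mean of
26; the actual 29 published-study weights are not distributed and no claim
of matching them is made.  Follow-up assigns each completer (default
fraction 1079/1620) an interval $U(5,7)$ years and a yearly drift
$\mathcal N(-0.02, 0.22^2)$ kg/m²/year, with optional structural
dependence of the drift on GPS or efficiency for power studies.  The
default seed is 20150514 and identical configurations are byte-identical
after serialisation.

### What the generator does and does not emulate

Passing tests on simulated cohorts show that the pipeline's algebra,
filters, and estimators behave as specified under the published marginal
structure.  They do not show that real cohort magnitudes are reproduced:
the generator has no linkage disequilibrium, no population stratification,
no questionnaire measurement error, no intake–expenditure dependence, and
no intervention feedback between a health check-up and subsequent weight
change.  Published headline magnitudes (r = −0.78 between BMI and
efficiency; adjusted $R^2$ = 0.66 for the efficiency models) were computed
on the original, non-deposited cohort and are treated as qualitative
ordering targets only.

### The sign of the BMI–efficiency correlation

The direction of that correlation deserves care.  Because the DEA output
is $1/BMI$, any BMI variation *not* explained by intake and expenditure
flows straight into the score with a negative sign — this is precisely why
the efficiency score is informative about non-environmental obesity, and
at the default noise level ($\sigma = 2.6$) the simulated correlation is
reliably negative, matching the published direction.  In a near-noiseless
cohort, however, the sign flips: eating more simultaneously raises BMI and
*shrinks* the inverse-intake input (making the subject look more
efficient), and when the frontier's intake share exceeds the BMI
elasticity of intake (about $\delta_{int}\,\bar t/\overline{BMI} \approx
0.19$ at the defaults) the intake channel dominates and the correlation
turns positive.  The sign-reproduction test therefore runs at the default
noise level, the condition the generator is calibrated to.

## Problem sizes used by the checks

The test suite solves the duality, units-invariance, dominance, and
frontier properties on hundreds of random instances of up to 50 DMUs;
parameter recovery fits the environment-plus-genetics model on 200
replicate cohorts of n = 2,000 and requires each generating coefficient to
fall within ±2 robust SEs in at least 90% of replicates; Hardy–Weinberg
proportions are checked at n = 10,000; end-to-end determinism is asserted
byte-for-byte on full pipeline reruns.  These sizes give stable Monte
Carlo behaviour for every assertion while keeping a full run of the suite
around a minute.

## Known limitations

* Radial CCR scores only: no variable returns to scale (BCC), no
  super-efficiency, slack-based measures, output orientation, or
  window/Malmquist extensions.
* Efficiency scores are *relative to the sample*: adding or removing
  subjects can move every score, so scores from different cohorts are not
  comparable.
* The multiplier-form weights and envelopment peer weights may be
  non-unique at degenerate vertices; only $\theta$ is contractual.
* Exact third-decimal agreement with commercial DEA software is not
  claimable, as such tools may apply their own internal rescaling and tie
  handling.
* The GPS assumes additive, independent loci with positive weights; no
  interaction or dominance terms.
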