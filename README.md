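# obesityDEA

Obesity has an environmental component (diet, exercise) and a genetic one.
`obesityDEA` quantifies both for every subject in an epidemiological
cohort:

* **Efficiency score** — each subject is a decision-making unit in an
  input-oriented, constant returns-to-scale (Charnes–Cooper–Rhodes) data
  envelopment analysis.  Inputs are physical-activity energy expenditure
  (METs-h/day) and the inverse of caloric intake (day/kcal); the output is
  the inverse of BMI (m²/kg).  For subject *o* the solver minimises the
  radial contraction θ subject to Σⱼ λⱼxᵢⱼ ≤ θxᵢₒ, Σⱼ λⱼyⱼ ≥ yₒ, λ ≥ 0; the
  optimum θ* ∈ (0, 1] equals 1 exactly when the subject lies on the
  empirical calorie-conversion frontier.  A low score flags obesity that is
  *not* explained by diet and exercise.
* **Genetic predisposition score (GPS)** — for L SNPs with effect-allele
  dosages aₗ ∈ [0, 2] and GWAS weights βₗ > 0,
  GPS = L·(Σ aₗβₗ)/(Σ βₗ) ∈ [0, 2L], after excluding SNPs with minor
  allele frequency < 0.5% or call rate < 95%.
* **Model comparison** — five MM-type robust regressions of baseline BMI
  (or yearly BMI change) on environment, efficiency, and GPS, all adjusted
  for age and sex, reported with robust standard errors and adjusted R².

A calibrated synthetic cohort generator (Hardy–Weinberg genotypes, an
additive gene + environment structural model for BMI, 5–7-year follow-up
with attrition) makes the whole pipeline testable without any subject-level
data.  The package is aimed at biostatisticians exploring DEA as a
personal-risk instrument in preventive medicine.

## Worked example

```r
library(obesityDEA)

cfg <- run_config(out_dir = tempfile(), seed = 1L,
                  sim = sim_config(n_subjects = 400L), log_level = "quiet")
res <- run_pipeline(cfg)

res$correlations[[1]]
#> r(bmi_baseline, efficiency) = -0.296, p = 1.49e-09, n = 400

res$baseline_models
#> Model comparison (bmi_baseline, mm):
#>     M1     M2     M3     M4     M5
#> 0.2875 0.1016 0.0131 0.2901 0.1040

res$baseline_models$fits$M5
#> M5 (bmi_baseline, mm): n = 400, adjusted R2 = 0.1040
#>         term estimate      se         p
#> 1  intercept 26.09931 1.54874 1.016e-63
#> 2  sex_woman -0.20005 0.29094 4.917e-01
#> 3        age  0.01665 0.01094 1.278e-01
#> 4        gps  0.04850 0.03655 1.845e-01
#> 5 efficiency -7.03158 1.23590 1.275e-08
```

Reading the output: BMI and the efficiency score are negatively correlated
— subjects who are heavier than their diet and exercise explain score as
less "efficient" — and the models containing the efficiency score (M2, M5)
carry more of the BMI variance than the genetics-only model (M3), the
qualitative pattern that motivates using DEA for environmentally driven
obesity risk.  In Model 5 each efficiency-score unit corresponds to about
−7 kg/m² here (the score spans ~0.5–1.0 in this simulated cohort).
`run_pipeline()` also writes `cohort_with_scores.csv`, `correlations.csv`,
`models_baseline_bmi.csv`, `models_bmi_change.csv` and
`quartile_summary.csv` (atomically, with the seed in each header) to
`out_dir`; reruns with the same seed are byte-identical.

A thin command-line wrapper is installed at
`inst/scripts/run_pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_pipeline.R", package = "obesityDEA"))')" \
  --out-dir results --n 1620 --seed 42
```

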