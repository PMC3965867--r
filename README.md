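# jmrecur

Joint modelling of a longitudinal antibody biomarker and recurrent
disease episodes with a shared random effect.

## The problem

In chronic relapsing autoimmune disease — the motivating setting is
pemphigus, a blistering disease monitored through serum IgG
autoantibody titers — two outcome processes are observed per patient:
a biomarker measured repeatedly over follow-up, and the recurrence
times of clinical episodes. Modelling them separately biases both
answers when they share patient-level heterogeneity. `jmrecur` is for
biostatisticians who want a fully parametric, likelihood-based joint
model for this design: a longitudinal linear mixed submodel and a
gap-time proportional-hazards submodel linked by a shared random
intercept.

## The model

For subject *i*, with titers transformed as `y = ln(1 + titer)`:

* Longitudinal submodel:
  `y_ij = x_ij' β + α_i + e_ij`, with `e_ij ~ N(0, σ_e²)` and random
  intercept `α_i ~ N(0, σ_α²)`. Covariates: age, sex, marital status,
  baseline lymphocyte value, and months since disease onset.
* Recurrent-event submodel on gap times `w_ik = t_ik − t_ik−1`:
  `h_i(w) = h_0(w) exp(z_i' η + γ α_i)`, a parametric proportional
  hazards model (Weibull or piecewise-constant baseline `h_0`) with the
  same `α_i` acting as a log-frailty. Covariates: age (standardized),
  sex, marital status, clinical phenotype (skin vs mucosal lesions).
* Given `α_i` the processes are conditionally independent; the
  association parameter `γ` measures how strongly high-titer patients
  are also recurrence-prone.

The marginal likelihood integrates `α_i` out per subject by adaptive
Gauss–Hermite quadrature (mode/curvature recentering, default order
15). Maximization uses staged initialization (separate submodel fits,
then joint polish), and inference uses observed-information standard
errors, Wald intervals, hazard ratios `exp(η)` and the per-month
percent change `100·(exp(β_time) − 1)`.

Because the motivating study's patient data were never deposited, the
package ships a calibrated synthetic-cohort generator
(`simulate_cohort()`) reproducing the study's design: 112 subjects,
monthly titers, mean follow-up 39.1 months, covariate mix as reported,
and a recurrence process in which ~10% of subjects experience more
than 5 episodes.

## Worked example

```r
library(jmrecur)

cohort <- simulate_cohort(generator_config(n_subjects = 112, seed = 7))
fit <- fit_joint(cohort, rule = quad_rule(9))
fit
```

```
Joint model: longitudinal ln(1 + titer) + recurrent gap times
  112 subjects, 4587 measurements, 419 episodes (307 events)
  log-likelihood -5477.496, converged (baseline: weibull, GH order 9, adaptive)
        block           term estimate       se   p_value   lower  upper
 longitudinal    (Intercept)   0.4460 0.196000  2.30e-02  0.0616 0.8310
 longitudinal            age   0.0373 0.002510  5.50e-50  0.0324 0.0422
 longitudinal           male   1.2800 0.082400  1.21e-54  1.1200 1.4400
 longitudinal         single   0.2370 0.140000  9.04e-02 -0.0373 0.5110
 longitudinal     lymphocyte   0.0328 0.004670  2.30e-12  0.0236 0.0419
 longitudinal           time   0.0230 0.000622 3.17e-299  0.0218 0.0242
    recurrent            age   0.2620 0.066600  8.22e-05  0.1320 0.3930
    recurrent           male  -0.1500 0.142000  2.89e-01 -0.4270 0.1270
    recurrent         single   0.3020 0.213000  1.56e-01 -0.1150 0.7190
    recurrent skin_phenotype   0.1140 0.118000  3.36e-01 -0.1180 0.3460
  association          gamma   0.9330 0.159000  4.23e-09  0.6220 1.2400
     variance        sigma_e   0.6060 0.006410        NA  0.5940 0.6190
     variance    sigma_alpha   0.4090 0.029000        NA  0.3560 0.4700
     baseline           rate   0.0595 0.010700        NA  0.0419 0.0845
     baseline          shape   0.9930 0.045800        NA  0.9070 1.0900
 transform transform_value
 ...        (pct/month 2.32 for time; HR column for the recurrent block)
```

Reading the output: titers rise an estimated 2.32% per month
(`100·(e^0.0230 − 1)`); single patients have a hazard ratio of 1.35
for recurrence; and the positive, strongly significant association
`γ = 0.933` (SE 0.159) says that patients whose underlying titer
level is high are the same patients whose episodes recur fast — the
joint model's headline quantity. The `variance` and `baseline` rows
are reported on their natural scales with log-scale Wald intervals.
This cohort was simulated at the package's default truth (γ = 0.876,
time trend 0.024), so the fit recovers those values to within its
standard errors.

`fit_table(fit)` returns this table as a data frame, `write_fit(fit,
"fit.json")` serializes everything at full precision, and
`recovery_study()` runs simulate-and-refit parameter-recovery
experiments. A thin command-line wrapper with `simulate`, `fit`,
`report` and `recover` subcommands is installed at
`inst/scripts/jmrecur.R`.

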