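# cavte

Simulation toolkit for a question that comes up in exposure-response (ER)
analyses of binary safety endpoints: **how does the way you impute the
reference time for censored subjects bias a CavTE-based logistic
regression?**

The time-averaged concentration to event,

```
CavTE(t_ref) = AUC(0, t_ref) / t_ref ,
```

uses the first-event time as `t_ref` for responders. Subjects with no event
by end of treatment (EoT) have no event time, so analysts impute one — EoT
itself, or EoT plus 7/14/21/28 days of follow-up. Because concentration
decays after the last dose, each added week of imputed follow-up lowers the
censored subjects' CavTE (a left shift of their exposure distribution) while
responders are untouched, steepening the fitted slope of the time-invariant
logistic model

```
logit P(event_i) = beta0 + beta * X_i ,      X_i = CavTE or Cav,ss
```

and shrinking its Wald p-value — a bias created by an analysis choice, not by
the data. This package generates the whole chain under known ground truth:

* **PK**: one-compartment oral model (first-order absorption, lag time,
  first-order elimination), 60 mg once daily for four 28-day cycles,
  log-normal between-subject variability (CL 17.7 L/h, 54% CV; V 229 L,
  34.1% CV; Ka 4.23 /h, 95.5% CV; Alag 0.154 h), closed-form concentration
  and cumulative AUC.
* **Adverse events**: ordinal Grade 0/1/2 proportional-odds model with
  Markov components; transition logits shifted by a saturable drug effect
  `s * Emax_prev * C / (EC50 + C)` that depends on the previous grade
  (Emax0 4.73, Emax1 1.09, EC50 6.05 ng/mL, 10% IIV on all parameters).
  Grades 1-2 are pooled to an any-grade endpoint; only the first event
  counts; grade-0-throughout subjects are censored.
* **Metrics**: CavTE under the five imputation policies (washout included
  beyond EoT) and Cav,ss = F·D/(CL·tau) as comparator.
* **Fitting**: `er_logistic()`, a Newton/IRLS logistic fitter returning a
  classed model object (`print`, `summary`, `coef`, `vcov`, `predict`,
  `simulate`, `residuals`) with Wald and likelihood-ratio slope p-values and
  explicit convergence/separation flags, plus quartile event-proportion
  summaries with Wilson intervals.
* **Scenario grid**: cohort sizes {50, 100, 200} x drug-effect scales
  {0.25 ... 1.5}, 200 replicates per cell, with the "<5% in either outcome
  class" skip rule and replicate summaries (median p, significant fraction,
  censored fraction, skip rate).

## Worked example

```r
library(cavte)

cfg <- scenario_config(n_subjects = 200, emax_scale = 0.75,
                       n_replicates = 1, seed = 20240101)
trial <- run_trial(cfg, replicate_seed = 12345)
trial[, c("metric", "beta", "p_slope", "n_event", "frac_censored")]
#>        metric       beta      p_slope n_event frac_censored
#> 1   CAVTE_EOT 0.01772947 2.331199e-04     168          0.16
#> 2  CAVTE_EOT7 0.02176712 5.317102e-05     168          0.16
#> 3 CAVTE_EOT14 0.02616534 1.239681e-05     168          0.16
#> 4 CAVTE_EOT21 0.03074869 3.091272e-06     168          0.16
#> 5 CAVTE_EOT28 0.03544933 8.639113e-07     168          0.16
#> 6       CAVSS 0.01837343 9.390848e-05     168          0.16
```

One simulated trial of 200 subjects at drug-effect scale 0.75: the same
cohort, the same 168 responders, the same responder exposures — yet the
fitted slope doubles and the slope p-value drops by three orders of
magnitude as the imputed follow-up for the 32 censored subjects grows from
EoT to EoT+28 days. Replicated summaries (`run_grid()` +
`replicate_summary()`) show the median p-value falling monotonically with
follow-up in every feasible cell, significance arriving earlier at larger n,
and censoring dropping below the 5% skip bound at scales >= 1.25.

A single fit, directly:

```r
coh <- simulate_cohort(pk_parameters(), ae_parameters(emax_scale = 0.75),
                       n = 200, seed = 1)
d <- build_er_dataset(coh$pk, coh$histories, dosing_regimen(),
                      "CAVTE", imputation_policy(28))
summary(er_logistic(d))
quartile_summary(d)
```

A thin CLI over the same functions ships in `inst/cli/cavte.R`
(`simulate`, `fit`, `grid`, `report` subcommands; YAML config with `pk`,
`ae`, `regimen`, `study` blocks).

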