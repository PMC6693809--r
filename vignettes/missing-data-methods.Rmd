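---
title: "Missing-data mechanisms, estimators and the simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-data mechanisms, estimators and the simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misslab)
```

This vignette is the package's account of its own methods: the models and
mechanisms it implements, the tunable parameters and why their defaults are
what they are, what the synthetic generators do and do not emulate, the
numerical choices, and the design of the Monte-Carlo verification grid.

## 1. Mechanisms and what "bias" means here

A missingness mechanism for a variable is written as a logistic model on
named *parents*: `P(missing) = logit⁻¹(α + Σ βⱼ·parentⱼ)`. Three classes
follow mechanically from the parent set (`classify_mechanism()`): no parents
is MCAR; a parent that is the variable's own value (token `.self`) or a
hidden latent score is MNAR; anything else is MAR. Binary parents enter as
0/1 and categorical parents as their 0-based level code, so β is a log-odds
per level step.

The quantity all verdicts and simulations refer to is the **exposure
regression coefficient** of the main analysis (linear or logistic). "CCA is
unbiased" means the complete-case estimator of that coefficient converges to
the generating value; the decisive question is whether the chance of being a
complete case depends on the *outcome* after conditioning on the model's
covariates. This gives the verdict table encoded in `cca_bias_verdict()` and
committed, fully enumerated (16 dependence sets × 2 models × 8 flag
combinations), in `inst/extdata/cca_verdict_golden.csv`; a test compares the
function against the file row by row. Two footnotes (zero true effect;
independent outcome and exposure mechanisms) and one caveat (a dichotomised
latent outcome whose underlying score drives missingness) complete the
rules.

## 2. Synthetic cohorts

Two generators provide complete data with known truth. Both are ordinary
structural equation systems sampled in causal order, bit-reproducible given
a seed, and fully overridable through their parameter constructors.

**Cannabis cohort** (`generate_cannabis_population()`): sex ~ Bernoulli(0.5)
and maternal substance use ~ Bernoulli(0.3); three-level cannabis use from
an ordinal logistic model on the two confounders (log-odds 0.4 and 0.9,
cutpoints 0.6 and 1.8, giving roughly 53/25/22% margins); a continuous
age-21 depression score from a linear model (effects 0.5 and 1.0 for the two
cannabis levels, 0.3 for sex, 0.6 for maternal substance use, residual SD 1);
and binary self-harm through a latent logistic score (same covariate
structure, intercept −1.6, dichotomised at zero, prevalence ≈ 25%). The
latent score is kept as a hidden column so mechanisms can depend on the
*continuous* propensity — the device behind the dichotomisation caveat.
Auxiliaries are an age-12 depression score generated as a correlation-0.7
proxy of the outcome and a conduct-disorder indicator driven by cannabis
use. No published parameters exist for this illustrative setting; the
defaults were fixed once so that (i) the exposure effect is large relative
to the outcome SD (the "weekly" contrast is one residual SD) and (ii) every
mechanism the verdict table calls biased produces bias detectable with high
power at the grid's scale (§6). They are study conditions, not tuning knobs.

**Growth cohort** (`generate_growth_cohort()`): covariates (birth weight,
sex, gestational-age category with reference 39–40 weeks, parental weights,
parental SES with reference III), the exposure (weight at age 5) from a
linear equation on the covariates, and adult BMI from the structural
equation whose coefficients are the cohort-analysis estimates that motivate
the example (weight-at-5 slope 0.458, maternal weight 0.0835, paternal
weight 0.0477, birth weight −0.788, sex 0.165, gestational <39 w 0.150,
>41 w 0.321, SES I/II −0.791, IV/V 1.20; residual SD 3.2, chosen to give a
realistic adult-BMI spread of ≈ 3.5–4 kg/m²). Auxiliary childhood
anthropometry (weight at 4.5 y, height at 5 y) is generated as noisy linear
proxies of the exposure with configurable correlation (defaults 0.7 and
0.5), the standard "surrogate data" device. The source tables label these
coefficients "Log OR" while describing a linear regression of BMI; the
package treats them as linear-model coefficients on the BMI scale, which is
the only reading consistent with their magnitudes.

What the generators deliberately do **not** emulate: the real cohorts' joint
covariate distributions (covariances among parental measures, secular
trends), longitudinal growth trajectories of the fourteen childhood
measures, or measurement error. Passing tests therefore show that the
*methods* behave as claimed under the stated mechanisms — not that any
particular real dataset is MAR.

## 3. Amputation

`ampute()` sets each targeted cell missing independently with its row
probability; values are never altered, only the mask, and the
pre-missingness truth stays readable through `shadow_values()` for
simulation diagnostics. Intercepts marked `"auto"` are calibrated against
the empirical parent distribution by monotone root-finding (`uniroot` on the
mean inverse-logit; achieved rate within 1e-8 — the mean probability is
strictly increasing in the intercept, so the root is unique).

The growth example additionally uses a *unit-level* mechanism: a logistic
model for being a complete case (odds ratios 0.913 per kg of weight at 5,
1.19 per kg birth weight, 0.721 for sex, 0.950 per kg maternal weight, 1.06
per kg/m² adult BMI; marginal incomplete fraction 404/951), with each
incomplete row losing a random non-empty subset of the six incompletely
observed variables. The per-variable deletion probabilities are proportional
to the motivating cohort's per-variable missingness counts
(272/141/45/8/3/1), and the subset is drawn independently of the covariates
— the real cell-level process is not published, so this is a design choice;
it preserves the completeness model's slopes exactly (eligibility acts as a
pure intercept shift) while producing the mixed multi-variable patterns a
pattern table should exercise. The canonical cannabis mechanisms (MCAR; MAR
on a confounder; MNAR on confounder + self; MAR on outcome + confounder;
MNAR on outcome + self; MAR on outcome only; independent outcome/exposure
mechanisms; latent-score dependence) live in `mechanism_catalog()` with
default missingness 40%, inside the 30–50% band the simulation design calls
for. Two catalogue strengths were set at design time for test power rather
than realism: the MNAR self-dependence of mechanism *c* is 1.5 log-odds per
level (a weaker dependence is almost entirely absorbed by the auxiliary
proxies in the imputation model, making the MAR-MI bias real but tiny), and
the latent-score coefficient of mechanism *h* is 2.0 (the selection
distortion of a dichotomised outcome is intrinsically moderate per unit of
dependence).

## 4. Estimators

`fit_ols()` solves weighted least squares by QR with an explicit rank check
(rank deficiency is an error, never a silent drop), classical variance when
unweighted and an HC0 sandwich on fixed weights when weighted. Linear
confidence intervals use t quantiles on the residual degrees of freedom.

`fit_logistic()` is Newton/IRLS with step-halving, so the log-likelihood is
non-decreasing (the trace is kept on the result and asserted in tests);
convergence at a maximum coefficient change below 1e-8 within 100
iterations; coefficients passing |β| > 30 raise a separation error rather
than returning a fit. Logistic intervals are Wald/normal. The sources do not
prescribe interval types; t-for-linear and normal-for-logistic is standard
epidemiological practice.

`fit_ipw()` estimates a logistic completeness model on fully observed
predictors, weights complete cases by 1/p̂ (probabilities floored at 0.01,
trims counted in the output), and refits with sandwich errors on the fixed
weights. Weight-estimation uncertainty is deliberately ignored — the
resulting intervals are conservative, and the output says so.

## 5. The MI engine

`impute_fcs()` is chained-equations (fully conditional specification)
imputation: initialise missing cells by draws from the observed marginal,
then cycle over incomplete variables in fixed column order, refitting each
conditional model on the rows where the target is observed and redrawing its
missing cells. Conditionals: Bayesian linear (σ² from its scaled inverse-χ²
posterior, β from its normal posterior, then predictive draws), logistic and
multinomial (maximum likelihood plus a normal coefficient perturbation using
the estimated covariance — the standard large-sample approximation to a
proper posterior draw; a bootstrap-then-fit variant is available via
`boot = TRUE` for small samples), and predictive mean matching (posterior-
draw predictions for observed and missing rows, uniform draw among the 5
closest donors by default, distance ties broken uniformly at random under
the run seed). A failed conditional (separation, rank deficiency) falls back
to PMM for that draw and is logged. Declared interactions are recomputed
passively after every update so imputation and analysis models cannot
disagree about them.

Defaults: 10 cycles (burn-in is cheap and the sources do not state a count),
m configurable with the motivating analysis using 50. The predictor matrix
defaults to *all* other non-latent variables — analysis variables including
the outcome, plus auxiliaries; `mi_analyze()` refuses an imputation model
for an analysis variable that omits the analysis outcome, since that is the
classic way to bias the analysis towards the null. Visit order is fixed
column order for reproducibility. Pooling follows Rubin's rules exactly
(`pool_rubin()`), with the large-sample degrees of freedom
`(m−1)(1 + W/((1+1/m)B))²` by default and the Barnard–Rubin small-sample
adjustment available through `df_com`; when B = 0 the degrees of freedom are
reported as infinite and T = W.

## 6. The verification grid

`run_grid()` runs every scenario in `scenario_catalog()`: the five
dependence rows × both model families for CCA (13 cells including the two
footnotes and the latent caveat), MI under mechanisms a/b/d/f (valid) and
c/e (biased), and IPW under mechanism d with the correctly specified weight
model. Complete-case cells take their expectation from `cca_bias_verdict()`
at run time, so the grid doubles as a consistency check of the decision
rules against simulation.

Scales, chosen once as desk-scale study conditions: CCA and IPW cells use
n = 2000 and R = 200 replicates; MI cells use n = 1000 and R = 120 with
m = 8 and a single chained-equations cycle — the grid mechanisms leave one
incomplete variable whose predictors are fully observed, so its conditional
model is independent of the initialisation and further cycles are redundant.
Two cells run more replicates because their true effects are moderate and
the bias test needs its designed ≥ 90% power: the MNAR MI cells (R = 300;
the MAR-MI bias under mechanism c is ≈ 0.05–0.06 once the auxiliaries are
conditioned on) and the latent-caveat cell (R = 500; selection on the latent
score biases the logistic exposure coefficient by ≈ −0.08).

The decision rule per cell: *biased* when the bias z-test has p < 0.001;
*unbiased* when |mean bias| ≤ max(3·MCSE, 2% of the true effect); anything
else is *inconclusive* and fails the cell. The 2% margin exists because
maximum-likelihood logistic estimates carry real finite-sample bias of a few
tenths of a percent at these sample sizes; measured at R = 3000 the
"unbiased" cells sit at |bias| ≈ 0.004, comfortably inside the margin, while
every "biased" cell sits at 0.05–0.33, far outside it.

`compare_efficiency()` packages the three efficiency demonstrations:
scattered 15% missingness on four continuous growth variables (MI beats CCA
on empirical SE, ratio ≈ 0.8); outcome-only missingness at 40% with no
auxiliaries, where the incomplete cases carry no information and MI's extra
Monte-Carlo noise is the whole story — that cell deliberately uses m = 5 so
the noise component (∝ B/m) is visible above replicate noise, which is
precisely the point being demonstrated; and a zero-correlation auxiliary as
the negative control (ratio ≈ 1). The auxiliary-gain property is tested in a
design with a weak outcome–exposure slope, because when the outcome strongly
predicts the exposure the outcome-only imputation model already recovers
most of what the auxiliary offers and the gain, though real, is too small to
resolve at test scale.

## 7. Diagnostics and the recommendation

`missingness_model()` regresses the complete-case indicator on chosen
predictors, restricted to rows where those predictors are observed — the
restriction changes the effective n, so the eligible count is reported. The
workflow chooses as predictors the outcome, the exposure and the confounders
with ≤ 5% missingness; conditioning on heavily missing confounders would
shrink the eligible rows towards the complete cases and degenerate the
indicator. "Completeness depends on the outcome" is operationalised as the
outcome term's 95% CI excluding an odds ratio of 1 — a threshold choice,
reported in the output and configurable through the significance level.

`refute_mcar()` runs per-candidate Wald tests of association with a
variable's missingness indicator, unadjusted by default (exploratory
framing; Bonferroni available) and is explicit that non-refutation cannot
separate MAR from MNAR. `incomplete_case_information()` turns the pattern
table into one of four categories (none / minimal / block-limited /
substantial); the qualitative notions need numeric cut-offs, so
"block-limited" means ≥ 75% of incomplete cases lose all covariate groups at
once, and the cut-offs are carried in the output for audit.
`recommend_method()` applies, in order: declared MNAR in the covariates with
outcome-independent completeness → CCA with an explicit warning that
MAR-based imputation would cause bias; outcome-dependent completeness, or
informative auxiliaries with informative incomplete cases → MI;
unbiased verdict with uninformative incomplete cases and no auxiliaries →
CCA; otherwise either, with IPW noted as the adjunct when the completeness
model is easier to specify than the imputation model. The five-point
checklist (CCA bias risk; auxiliaries predict missingness; incomplete cases
informative; auxiliaries predict values; sufficient observed information) is
attached with evidence so the recommendation is reproducible from its own
output.

## 8. Known limitations

Classification of mechanisms is syntactic (by declared parents): data alone
cannot distinguish MAR from MNAR, and the package never claims to. The MI
engine covers cross-sectional rectangular data only — no survival outcomes,
no multilevel structure, no joint-modelling or hotdeck imputation, and no
delta-adjusted MNAR sensitivity analysis. IPW variance ignores weight
estimation (conservative). The logistic/multinomial posterior perturbation
is a large-sample approximation; for very small samples use the bootstrap
variant. The growth generator reproduces a published coefficient vector and
missingness model, not the real cohort's joint distribution; conclusions
about the real data remain conditional on its own, unverifiable,
missingness assumptions.
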