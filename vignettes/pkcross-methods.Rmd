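---
title: "Models and methods behind pkcross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pkcross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkcross)
library(dplyr)
```

`pkcross` implements the analysis chain of a phase I crossover
pharmacokinetic (PK) and drug–drug interaction (DDI) study of IV-infused
drugs: simulate (or import) subject-level plasma and urine data,
noncompartmental analysis (NCA), geometric LS-mean ratio equivalence
testing against 80–125% limits, and the associated power calculation. This
vignette explains the models, the estimators, the default calibrations and
the choices made where the design was genuinely open.

## The disposition model

Doses are constant-rate IV infusions (rate $R_0 = \text{amount}/T_{inf}$,
no lag). Disposition is linear and time-invariant, one- or two-compartment.
Writing the unit-bolus response as a sum of exponentials
$c_\delta(t) = \sum_i A_i e^{-\lambda_i t}$, the single-infusion
concentration is obtained in closed form by integrating $c_\delta$ over the
infusion window, and multiple dosing is plain superposition over dose
events. Two identities anchor the implementation and are enforced by
property tests: $\mathrm{AUC}_\infty = \text{dose}/\mathrm{CL}$, and the
amount excreted in urine over $[t_0, t_1]$ equals
$f_e \cdot \mathrm{CL} \cdot \mathrm{AUC}(t_0, t_1)$ with renal fraction
$f_e$, so the total recovery of a single dose is $f_e \cdot \text{dose}$
(mass balance).

Units are fixed internally: hours, mg, L, µg/mL. Parameters are calibration
choices, not estimates from data: the purely noncompartmental source
analysis implies no structural model, so the defaults are one-compartment
models matched to the reported clearances and terminal half-lives
(ceftazidime CL 7 L/h, $t_{1/2}$ 2.7 h, $f_e$ 0.95; avibactam CL 12 L/h,
$t_{1/2}$ 2.3 h, $f_e$ 1 — avibactam is essentially completely renally
cleared; metronidazole CL 4.35 L/h, $t_{1/2}$ 8.4 h). A one-compartment fit
cannot match the observed C~max~ and AUC simultaneously (real profiles are
multiphasic), and the defaults prioritise AUC, clearance and half-life —
the quantities the acceptance surface depends on. A two-compartment model
is available behind the same interface when profile shape matters.

A consequence worth noting: the textbook accumulation factor
$1/(1-e^{-\lambda_z \tau})$ is exact for bolus input only. For an extended
infusion the exact steady-state factor is
$\mathrm{AUC}_\infty / \mathrm{AUC}_{0\text{–}\tau}(\text{single dose})$
(≈ 1.20 rather than 1.15 for $t_{1/2}$ 2.7 h, $\tau$ 8 h, 2-h infusion);
tests check the bolus form in the bolus limit and the infusion-exact form
for the 2-h-infusion pipeline.

## The synthetic-data generator

`simulate_crossover()` emulates the three study configurations: an 11-day
multiple-dose PK study (single dose Days 1/11, q8h Days 2–10, n = 16) and
two 3-way crossover DDI studies with 4-day periods (single dose Days 1/4,
q8h Days 2–3; n = 27 and n = 28), washout ≥ 48 h, the studies' nominal
blood-sampling schedules (per treatment in the metronidazole study, where
all times are relative to the start of the first infusion) and urine
collections over 0–2, 2–4, 4–8, 8–12 and 12–24 h.

Variability has three components:

* **Between-subject** — a log-normal subject-level size factor applied
  jointly to CL and V (SD `between_subject_sd_log`). The source analysis
  reports no between-subject variance estimate, so the default is a
  geometric CV of 15%, matching the magnitude of the reported CV% columns;
  applying it to CL and V jointly makes AUC and C~max~ co-vary the way a
  body-size effect does.
* **Within-subject** — a log-normal period-level multiplier of variance
  $\sigma_w^2$, implemented as $(\mathrm{CL}, V) \to (\mathrm{CL}/m, V/m)$.
  This scales the whole curve by $m$ with shape preserved, so the
  within-subject SD of log C~max~ (and log AUC) *equals* $\sigma_w$ — the
  parameterization the power calculation assumes (default 0.2171, the
  ceftazidime log-C~max~ value; 0.2088 for avibactam) — while the excreted
  amount $f_e (\mathrm{CL}/m)(m \cdot \mathrm{AUC})$ is unchanged, keeping
  urinary mass balance exact. A multiplier on CL alone would attenuate the
  log-C~max~ SD several-fold for these kinetics and break the
  moment-recovery property.
* **Assay noise** — independent proportional noise on each measurement
  (default CV 5%, consistent with the reported assay precision).

Sampling times are nominal (`actual_time = nominal_time`); the reported
t~max~ ranges (2.00–2.02 h) show deviations too small to matter here.
Concentrations below the analyte LLOQ (metronidazole 0.040 µg/mL;
ceftazidime 0.0446, avibactam 0.010) are flagged BLQ with the value
withheld; the comparison is strict, so a value exactly at the LLOQ is
retained. Day-1 predose samples are generated and are BLQ by construction.
Periods are simulated independently: washout ≥ 48 h is > 17 terminal
half-lives for the β-lactams, so carryover is negligible and not modelled.
Each subject draws a dedicated RNG stream derived from the master seed, so
output is byte-identical across reruns and stable in structure.

What the generator does **not** emulate: sampling-time jitter (optional in
real datasets), assay calibration drift, dropouts and protocol deviations,
multiphasic distribution (under the default one-compartment settings), and
any true interaction effect — the simulation truth is always "no
interaction", which is exactly what makes it a null-calibrated test bed.
Passing tests therefore demonstrate internal consistency of the estimators
under the stated variability model, not robustness to real-data pathology.

## Noncompartmental analysis

* **AUC** uses linear-up/log-down trapezoids: rising segments (or segments
  touching 0) contribute $(C_1+C_2)\Delta t/2$; falling positive segments
  contribute $(C_1-C_2)\Delta t/\ln(C_1/C_2)$. Partial bounds are
  interpolated by the same rule (log-linear on falling segments). The rule
  is exact for mono-exponential decline between samples.
* **BLQ handling** (the source is silent; common NCA default): leading BLQ
  samples enter the AUC grid as 0, embedded and trailing BLQ samples are
  excluded from both the AUC grid and the terminal fit.
* **$\lambda_z$** is fit by OLS of $\ln C$ on $t$ over quantifiable points
  strictly after t~max~. The source does not state a point-selection rule;
  the package uses the standard convention: candidate windows are the last
  $k = 3, 4, \dots$ points, the maximal adjusted $R^2$ wins (ties within
  $10^{-4}$ to the larger window). The fit is not reportable when
  $R^2 < 0.8$ or the slope is nonnegative.
* **Gates**: $\mathrm{AUC}_\infty = \mathrm{AUC}_{last} + C_{last}/\lambda_z$
  is suppressed — along with $t_{1/2}$, CL and the linearity index — when
  the extrapolated share exceeds 20% or the $R^2$ gate fails. Exactly this
  parameter set is suppressed (the reported table footnotes list it);
  AUC~0–τ~, C~max~ and t~max~ survive. Every gating event is recorded in a
  `flags` column and in the pipeline log.
* **AUC~0–τ~** uses $\tau$ = 8 h on all days, including Day 1 where
  sampling extends to 24 h (the AUC "during the dosing interval").
* **CL~R~** divides the urinary amount over the collection span common to
  plasma sampling (0–24 h) by the plasma AUC over the same span.
* **Summaries** follow the usual table conventions: geometric mean with
  geometric CV% $= 100\sqrt{e^{s^2}-1}$ ($s$ = sample SD of natural logs,
  $n-1$ denominator) for concentrations and AUCs, median (range) for
  t~max~, arithmetic mean (SD) for $t_{1/2}$ and clearances. Rounding
  (3 significant figures for concentrations/AUCs, 1 decimal for ratios and
  clearances, 2 for t~max~; half-up) is applied only in the reporting
  layer; all underlying CSVs carry full precision.

## Equivalence analysis

The estimand is the treatment contrast of the log parameter in a linear
mixed model with sequence, period and treatment fixed effects and subject
nested in sequence as random effect. For complete, balanced crossover data
that LS-mean difference equals a simple function of within-subject
contrasts, which is what `ls_mean_ratio()` computes: per-subject
log-differences $d_i$ (test − reference), grouped by the period pattern in
which the pair was received; the estimate is the unweighted mean of
pattern-group means (cancelling additive period effects) and the variance
is pooled within patterns. With one pattern this is the paired $t$ contrast
with $n-1$ df; with $G$ patterns the df are $n-G$. A test verifies equality
with the `lm()` fixed-effects fit on balanced data. Subjects missing either
treatment are excluded per contrast and counted — mirroring how studies
exclude individual subject-days with abnormal profiles. The df convention
for unbalanced mixed-model software can differ; the package documents its
own rather than guessing another implementation's.

The ratio is $100 \cdot e^{\hat\delta}$ with a 90% CI; "no interaction"
requires every planned contrast's CI inside the closed interval
[80%, 125%] — a CI touching a bound exactly still passes, a convention made
explicit because printed CIs are rounded. Day-1 contrasts use
AUC$_\infty$ and C~max~; steady-state (Day-4) contrasts use AUC~0–τ~ and
C~max~.

**Power.** For the TOST procedure with true log-ratio $\theta$, SE
$\sigma_w\sqrt{2/n}$ and $n-2$ df (the crossover mixed-model convention),
the exact power integrates the normal rejection probability over the
$\chi^2$ distribution of the variance estimate — equivalent to Owen's Q —
with `integrate()` at relative tolerance $10^{-9}$. The $\sigma_w = 0$
limit returns 1 strictly inside the limits and 0 otherwise. The simulation
twin draws paired log-differences $N(\theta, 2\sigma_w^2)$ and applies the
same paired-$t$ CI vectorized across replicates ($n-1$ df; the one-df
difference from the analytic routine is far below Monte-Carlo resolution
at the sizes used, and a test pins the vectorized analysis to
`ls_mean_ratio()` on individual replicates). At the design point
($n = 24$, $\sigma_w = 0.2171$, limits 0.8–1.25, $\alpha = 0.05$) the
analytic power is 0.929, confirming the ≈ 90% design claim.

## Numerical and testing choices

Problem sizes were chosen to make each check informative at interactive
cost: variance-component recovery uses 1000 subjects (2000 subject-periods,
recovering $\sigma_w$ within 5%); simulated-vs-analytic power agreement and
boundary type-I error use 4000–10 000 replicates (MC SE < 0.005); the
remaining properties run on studies of 2–27 subjects. Closed-form oracles
(dose/CL, mass balance, bolus accumulation) and independent numeric oracles
(ODE integration, fine-grid interpolant quadrature, brute-force terminal
window enumeration) back every derived value frozen in the tests.

Known limitations: no nonlinear or absorption kinetics; no carryover or
true period effects in the generator (the estimator handles them, the
simulator does not inject them by default); no REML machinery for
arbitrarily unbalanced designs; sparse-sampling NCA and partial AUCs beyond
(0–τ)/(0–last) are out of scope.
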