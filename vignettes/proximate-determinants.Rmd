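---
title: "Decomposing fertility with the proximate-determinants model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing fertility with the proximate-determinants model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdfert)
```

## The model

The Bongaarts proximate-determinants framework treats the total fertility
rate as the biological maximum (total fecundity, `TF`) multiplied down by
four inhibition indices:

$$\mathrm{TFR} = C_m \times C_c \times C_a \times C_i \times TF$$

Each index isolates one behavioural or biological pathway; each equals 1
when that pathway does not inhibit fertility at all. The model assumes the
four pathways act multiplicatively and independently, and that everything
else (primary sterility, spousal separation, coital frequency, ...) lands
in the *residual* between predicted and observed fertility. `pdfert`
implements the model for DHS-style woman-level microdata: survey-weighted
rates in the seven five-year age groups 15–19 … 45–49, aggregate indices,
predicted fertility, and log-scale percent contributions,

$$\text{share}_k = 100\,\frac{\ln C_k}{\sum_j \ln C_j},$$

which sum to 100 whenever at least one index is below 1.

### Index of marriage

`Cm(a) = m(a)`, the weighted proportion currently married; the aggregate is
the marital-fertility-weighted mean with `w(a) = f_m(a)/Σ f_m(a)`. Marital
fertility is estimated from the retrospective birth history (births over
married woman-years of exposure, classified by age at the event). Because
very few 15–19-year-olds are married, the observed 15–19 marital rate is
noisy; it is *always* replaced by 0.75 times the 20–24 rate, the standard
stabilisation. When a subpopulation (for instance an age band) has no
women at all in some groups, those groups drop out of the aggregate and
the weights renormalise over the groups present.

### Index of contraception

`Cc(a) = 1 − r(a)·(u(a) − o(a))·e(a)` among currently married women, where

* `u(a)` is any-method contraceptive prevalence;
* `o(a)` is the *overlap* of use with infecundability: the weighted share
  of married women who are using a method while either still postpartum
  insusceptible (their longest postpartum factor has run to the present)
  or within three years of a non-contraceptive hysterectomy — protection
  that overlaps a period when they could not have conceived anyway;
* `e(a) = Σ_m e(m)·u(m,a)/u(a)` is the use-weighted mean method
  effectiveness;
* `r(a)` adjusts prevalence for the concentration of use among fecund
  women; defaults `(0.62, 0.81, 0.99, 1.08, 1.14, 1.26, 1.62)`.

The aggregate uses natural-fertility weights `w(a) = f_n(a)/Σ f_n(a)`. How
`f_n` was obtained is genuinely open in published applications; the
package uses the natural age-specific fecundity schedule `f_star`
(`0.484, 0.540, 0.531, 0.448, 0.290, 0.167, 0.109` births/woman-year) as
the proxy, and accepts a user-supplied schedule via the `f_n` argument.
The default effectiveness table (sterilization 0.995, IUD 0.985,
injectable 0.97, pill 0.92, condom 0.87, traditional 0.75, other 0.80) is
an order-of-magnitude standard and deliberately overridable: published
applications cite failure-rate compilations without printing values.

### Index of postpartum infecundability

Per woman, the duration of infecundability is the *longest* of full
breastfeeding, postpartum amenorrhea and postpartum abstinence (for women
with a birth in the 36 months before interview), or the months since a
non-contraceptive hysterectomy (within the same window). `i` is the
weighted mean over eligible women and `Ci = 20/(18.5 + i)`, capped at 1.
Two readings of the mean's denominator are possible — all women, or
eligible women only; the package implements the eligible-women reading
(the factors are undefined for other women), which is also what makes the
synthetic truth exact.

### Index of induced abortion

`Ca = TFR/(TFR + b·TAR)` with `TAR = 5 Σ ab(a)` and `b = 14/(18.5 + i)`
births averted per abortion. The source formula for `b` is printed
ambiguously ("14(18.5+i)"); the package reads it as a quotient by analogy
with `Ci` — the other reading would give `b > 250`, implying each abortion
averts hundreds of births. Both the constant and the reading are exposed in
`pd_constants()`. The aggregate formula is used throughout; the
age-specific aggregation path is deliberately not taken.

Subgroups rarely have direct abortion estimates. The package allocates an
aggregate abortion count across the categories of a stratifier in
proportion to each category's weighted share of women with *unmet need*
for contraception (`allocate_abortions()`), conserving the total exactly.
For states with a known overall rate, the national age schedule can be
rescaled (`adjust_state_age_rates()`); the default multiplies by
`R_state/R_national`, which preserves the state's overall rate. The
printed description of this adjustment multiplies by the inverse ratio,
which would not preserve the state total; that literal convention is
available as `mode = "literal"` so both can be compared.

An overall rate per 1000 women 15–49 converts to a TAR under a flat age
schedule: `TAR = 35 × rate/1000` (`tar_from_overall_rate()`).

## Stratified runs and suppression

`run_decomposition()` produces one row per stratum: national, each state
(abortion rate resolved state → region → national, the source recorded per
row), and any of residence/education/wealth/caste/age-band (abortion by
unmet-need allocation). Cells under 50 unweighted women are fully
suppressed; 50–100 are flagged; under 25 unweighted recent births the
infecundability chain (Ci, TFRe, residual, shares) is suppressed; 25–50
flagged. Suppression depends only on unweighted counts; estimates use
weights throughout. Suppressed values are emitted as `NA`, never as
numbers.

Two percent contributions are deemed significantly different when they
differ by strictly more than 5 percentage points
(`significance_flag()`) — with four determinants contributing 25 points
each, 5 points is a 20% relative change.

## The synthetic cohort and its closed-form truth

`generate_cohort()` draws a cohort whose every downstream quantity is
known exactly, so parameter recovery — not just unit behaviour — is
testable. The process:

* age uniform on 15–49 (exact age taken as completed age + 0.5);
* marriage Bernoulli with the current group's `prop_married`;
* births: for married women, one Bernoulli trial per month over the
  36-month window with probability `fertility_rate(g)/12`, `g` being the
  group the woman occupied *at that month* (no risk before exact age 15).
  This makes the retrospective ASFR estimator exactly unbiased, and makes
  recent-birth prevalence an implication of the fertility rates rather
  than a separate — potentially inconsistent — parameter;
* postpartum durations: truncated exponentials on [0, 36] months (floored
  to whole months, capped at months since the most recent birth). Integer
  months match survey coding and make "factor still ongoing" an exact
  test (`duration == months elapsed`) that survives text round-trips;
* non-contraceptive hysterectomy only among married women *without* a
  recent birth (keeping the two eligibility classes for `i` disjoint, so
  the truth is exact), timing uniform over 1–36 months;
* contraceptive use Bernoulli with `u(g)`, method from `method_mix`,
  independent of postpartum status; unmet need among married non-users;
* stratifiers independent, except region, a function of state.

`cohort_truth()` computes the implied `m(a)`, `f_m(a)`, `f(a)`, TFR,
`u(a)`, `o(a)`, `e`, `i`, `Cm`, `Cc`, `Ci` by exact enumeration over the
35 single-year ages and 36 monthly trials — deterministic arithmetic, no
simulation. The truth applies the same 15–19 imputation as the pipeline,
and the default `fertility_rate` schedule satisfies the imputation
identity already, so no artefactual gap arises.

Defaults emulate the broad structure of the Indian 2015–16 survey round:
marriage rising from 0.16 (15–19) to ~0.9, a sterilization-dominated
method mix, postpartum factor means of 5/7/3 months (breastfeeding /
amenorrhea / abstinence), hysterectomy probability 0.01 in the window, and
declining unmet need with age. Under these defaults the implied TFR is
about 2.9.

What the generator does **not** emulate: multistage cluster sampling and
design effects (weights are constant, or i.i.d. lognormal under the
`"lognormal"` option), marriage-status changes within the window,
correlation between contraceptive use and postpartum status, birth-spacing
constraints, and item non-response. Passing recovery tests therefore
demonstrates estimator correctness under the stated process, not
robustness to real-survey pathologies.

## Numerical conventions

* Indices are clipped to [0, 1] (with a warning) before aggregation, and
  floored at `1e-6` before logs in the share decomposition; a zero index
  would otherwise make its log-share undefined.
* If all four indices equal 1 there is no reduction to attribute; shares
  are `NA` with a warning, not 0/0.
* `TFRa = 5 Σ f(a)` over groups with positive exposure; in full
  populations this is all seven groups.
* Empty age groups yield `NA` rates and drop out of aggregates with
  renormalised weights; an all-`NA` schedule is an error.
* Rounding (indices and TFRs to 2 decimals, shares to 1) happens only at
  serialisation (`write_results()`); all internal computation is full
  precision.
* Records violating invariants are rejected row-by-row at read time with
  indexed diagnostics, never silently repaired; unknown stratifier
  categories are errors, not pooled.
* Missing duration codes are excluded from means rather than imputed.

## Test problem sizes

Parameter-recovery tests generate 50,000 women and compare the estimated
`Cm`, `Cc`, `Ci` to the closed-form truth within 3 Monte-Carlo standard
errors; the standard errors (0.0044, 0.0028, 0.0015 at that size) were
measured by an independent 30-replicate simulation of the generator.
Schedule-level recovery uses binomial standard errors with a family-wise
band across the 14 simultaneous comparisons. Faster unit and property
tests use cohorts of 1,200–6,000 women and hand-constructed records with
known answers.

## Limitations

* Abortion incidence is taken as given; the package does not estimate it,
  and the unmet-need allocation is an assumption, weakest at the oldest
  ages (hence the state age-rate rescaling).
* No design-based variance estimation: published applications report no
  uncertainty for the indices, and the suppression rules stand in for
  formal inference.
* The 36-month retrospective window is a convention (configurable via
  `asfr_window`); published tables do not state their reference window.
* `TF = 10.9` and the `f_star` schedule are external constants applied to
  every stratum; heterogeneous fecundity shows up in the residual.
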