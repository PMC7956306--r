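---
title: "Converting retirement pensions into long-term-care support: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting retirement pensions into long-term-care support: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcfactor)
```

## The problem

A retiree in a defined-benefit pension scheme who becomes severely or highly
dependent faces long-term-care (LTC) costs precisely when their remaining
lifetime is shortest. Because dependent lives carry substantially higher
mortality than independent lives, the *expected number* of pension payments
they will collect drops at the moment of dependency. `ltcfactor` implements
the actuarial mechanism that exploits this: on certified severe dependency,
the annual pension $b$ is rescaled to $b\,\lambda^d_x$, where

$$\lambda^d_x = \frac{e_x}{e^d_x}$$

is the ratio of independent to dependent life expectancy at the age $x$ of
conversion. The beneficiary receives a higher payment over a shorter
expected horizon; the expected total payout — and hence the scheme's cost —
is unchanged. No new contributions, premiums or deductions are involved.

## The survival model

Everything is built on discrete-annual cohort life tables. A `life_table`
holds annual death probabilities $q_x$ for one sex, cohort and health state,
closed so that $q_\omega = 1$; survivors $l_x$, survival probabilities
${}_tp_x = l_{x+t}/l_x$, the piecewise-constant force of mortality
$\mu_x = -\log(1-q_x)$, and life expectancies all derive from it. The
underlying theory is usually written in continuous time; since every
published result the package reproduces is an annual-grid table, the
implementation is discrete throughout, with $\mu_x$ as the exact
constant-intensity bridge to the continuous formulation. (The discrete
expectancy is checked in the test suite against numerical quadrature of the
continuous survival function on Gompertz–Makeham laws; they agree to a few
tenths of a year.)

Two expectancy conventions are exposed because sources rarely state theirs:
*curtate* ($e_x = \sum_{t\ge1} {}_tp_x$, whole years) and *complete*
(curtate $+\tfrac12$). The default is complete, which is what integral
definitions of $\lambda$ imply. A third convention, `"annuity_due"`, is the
ratio of zero-interest annuity-due values $(1+e_x)/(1+e^d_x)$ with both
expectancies truncated at the terminal age $w$; it exists because it is the
convention under which the cost-free property below is an exact identity.

Abridged (5-year) schedules are ingested by linear interpolation of
$\log q_x$ across gaps of up to 4 missing years; on smooth adult schedules
this recovers single-age rates to well under 5% relative error. A schedule
that never reaches $q=1$ is closed by log-linear extrapolation of $q$ up to
a terminal age of 120 (capped at 1). Both are pragmatic choices: the shipped
fixture stops at age 100 with $q$ far below 1, so *some* closure assumption
is unavoidable, and for that reason the package never claims to reproduce
the fixture's printed expectancy columns from its printed $q$ columns —
those embody the publisher's own undisclosed closure.

## Dependent-lives excess mortality

Dependent mortality is modelled as a correction of general mortality that
preserves the ordering $q^d_x \ge q_x$. Three corrections are provided:

* **multiplicative**: $q^d = \min(\theta q, 1)$, $\theta \ge 1$ — adequate
  at old ages but biased across the age range;
* **additive**: $q^d = q + \varepsilon(x)$, clipped to $[0,1]$, with any
  user-supplied age profile $\varepsilon$;
* **mixed** (the canonical instance): a logistic-in-age additive excess
  plus, from a switch age, a multiplicative loading,

$$q^d_x = \begin{cases} q_x + \dfrac{\delta}{1+\gamma^{x_i-x}} & x < 95\\[2ex]
q_x(1+\beta) + \dfrac{\delta}{1+\gamma^{x_i-x}} & x \ge 95.\end{cases}$$

Here $\delta$ is the asymptotic maximum additive excess (probability
scale), $\gamma > 1$ the slope, $x_i$ the inflection age at which the excess
is exactly $\delta/2$, and $\beta$ the old-age loading that reflects the
narrowing of absolute differentials at extreme ages. Fitted values for
severe/high dependency in Spain ship as presets:

```{r presets}
excess_preset("spain_severe_men")
excess_preset("spain_severe_women")
```

Three numerical choices deserve note. First, the piecewise condition is
interpreted as a condition on attained age (parameterised as `switch_age`,
default 95): a condition on the constant $x_i$ would be degenerate, and the
attained-age reading matches the documented narrowing of differentials from
the mid-90s. Whether the loading should bind from exact age 95 or 96 is
ambiguous in the sources; the package uses $x \ge$ `switch_age`. Second, the
logistic exponent is implemented as printed, $\gamma^{x_i-x}$, which makes
the additive excess *increase* with age when $\gamma > 1$; a `"mirrored"`
$\gamma^{x-x_i}$ variant is available for experimentation. Third, the two
branches need not join continuously at the switch age; rather than smoothing
the jump away, `derive_dependent_table()` reports its magnitude in the
`switch_jump` attribute. Corrected probabilities are clipped to $[0,1]$ and
the ordering $q^d \ge q$ is enforced post-clip; a correction that violates
it anywhere is an error, not a warning.

`fit_excess_params()` estimates $(\delta,\gamma,x_i,\beta)$ from paired
(general, dependent) rates by ordinary least squares. The residual surface
is multimodal in $(\gamma, x_i)$, so a coarse multistart grid (five slopes
× four inflection-age quantiles × two loadings) seeds bounded L-BFGS-B,
and the best start is polished with Levenberg–Marquardt. On noiseless data
generated from the model itself, parameters are recovered to better than
$10^{-3}$ with residual sums of squares near machine zero; recovery of
$\beta$ requires observations above the switch age.

## The conversion schedule

`build_schedule()` tabulates, per age: $\lambda$, both expectancies, the
relative excess mortality $q^d/q - 1$, the literal difference (`abs_excess`),
the female-over-male dependent-mortality differential
$q^d_{f}/q^d_{m} - 1$, and the expectancy gap $e_x - e^d_x$ — which, under
annual payments, *is* the expected number of payment-years forgone by a
dependent retiree. The ratio-minus-one reading of the published comparison
columns is deliberate: it is the only reading consistent with the printed
reference values the package reproduces, and the literal subtraction is kept
available under its own name.

Two input modes share the schedule type. Full-table mode computes
expectancies from `life_table` objects and is used for synthetic data.
Fixture mode takes printed abridged $(q, e)$ values verbatim — as in the
shipped 1970-cohort Spanish table — and computes $\lambda$ directly from the
printed expectancies, avoiding the closure assumptions a rebuilt table would
inject. At a handful of printed ages the published $\lambda$ differs in the
last digit from the rounded-expectancy ratio (unrounded internal
expectancies, evidently); the package reproduces exactly the cells that
round cleanly and makes no claim about the others.

## Cost-free equivalence

The central theorem-like property: with benefit level $b$, zero interest,
and $\lambda$ computed under the `"annuity_due"` convention truncated at the
same terminal age $w$ as the annuity, the present values of the retirement
annuity and the converted LTC benefit coincide identically,

$$\lambda \cdot PVFB^{dep}_x = PVFB^{ind}_x,$$

because both sides reduce to $b$ times the same truncated survival sums.
`check_equivalence()` returns the relative residual; the test suite verifies
it is below $10^{-12}$ across parameter sets, laws and ages. At positive
interest the expectancy-ratio $\lambda$ is an approximation: the dependent
annuity is front-loaded and discounts less severely, so the residual is
positive and grows with the interest rate. The package reports this gap
honestly rather than silently redefining $\lambda$ as a ratio of discounted
annuity values — though users who want exact equivalence at positive
interest can compute exactly that ratio from `pvfb()`.

Present values use an annual annuity-due discretisation (payments at the
start of each survived year, from $x$ to $w-1$), consistent with the annual
$q$ grid and with pension practice; annuity-immediate timing is a switch.
Discounting is exact for piecewise-constant interest intensities.

## The multistate model

The population structure is a discrete annual multistate chain — active,
retired, dependent, disabled, dead — with one transition per year and no
return to previous states. `validate_rows()` checks the per-phase closure
identities (probabilities summing to 1) and reports rather than throws.
`project_cohort()` is a deterministic expected-count projection that
conserves total mass to $10^{-9}$ and treats death and disablement as
absorbing; disability carries no benefit logic here, since lower dependency
degrees route to disability pensions outside this mechanism's scope. The
retiree's conversion choice is exogenous: a 0/1 per-age indicator, monotone
once taken. Where the indicator is 0 the dependent-transition mass stays in
the retired state (the retiree keeps the pension), keeping rows closed. A
seeded Monte-Carlo sampler (`simulate_cohort()`) is provided for
illustration; the deterministic projection is the reference.

## Synthetic data, and what the tests do and do not show

No public dependent-lives table exists for the population the fixture
describes, and the general table behind it is proprietary. The synthetic
generator therefore uses a Gompertz–Makeham law, $\mu_x = A + Bc^x$, with
exact annual integration $q_x = 1-\exp(-A - Bc^x(c-1)/\log c)$ — a smooth,
strictly ageing adult schedule, which is all the method requires. Defaults
($A=2\times10^{-4}$, $B=3\times10^{-5}$, $c=1.1$) give an adult mortality
schedule of plausible insured-lives shape. `make_dependent_pair()` produces
an (independent, dependent) pair in which the dependent table is *exactly*
the mixed-correction image of the base — the round-trip oracle for the
fitter. Random noise for fitting experiments is controlled by an explicit
seed (default 20210225).

What passing tests show: the algebraic pipeline — table construction,
corrections, $\lambda$, present values, projection — is internally
consistent, reproduces the printed reference statistics from the printed
inputs, and satisfies the cost-free identity exactly at its stated limit.
What they do not show: that a Gompertz–Makeham law describes any real
population, that the Spanish presets transfer to other populations, or that
printed-fixture expectancies could be re-derived from first principles
(they cannot, absent the publisher's closure and generational adjustments).
Cohort year is metadata: no mortality-improvement projection is applied.

## Problem sizes

The test suite and the acceptance script run on the 17-row printed fixture,
synthetic tables over ages 20–120, fitting problems of 40–71 observations,
and projections of up to 40 annual steps — sizes chosen to match the
published tables and to exercise every branch of the model.

## Known limitations

* Single-decrement annual grids only; no monthly decrements, no multi-year
  or semi-Markov transitions, no recovery from dependency.
* The conversion decision is not behavioural; no selection or correlation
  between dependency incidence and mortality is modelled.
* $\lambda$ is degree-blind: only severe/high dependency converts, with no
  excess mortality (and no conversion) at moderate degrees.
* The equivalence is exact at zero interest only; at realistic rates the
  conversion slightly over-funds the LTC benefit, by an amount
  `check_equivalence()` quantifies.
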