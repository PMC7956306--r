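# ltcfactor

Actuarial toolkit for converting a defined-benefit retirement pension into a
long-term-care (LTC) support benefit **at no added cost to the scheme**.

## The problem

A retiree who becomes severely or highly dependent needs more money per year
— for care — over a shorter remaining lifetime, because dependent lives
carry much higher mortality than independent lives
(q<sup>d</sup><sub>x</sub> ≥ q<sub>x</sub>). `ltcfactor` implements the
mechanism that turns this into a benefit: on certified severe dependency,
the annual pension *b* is rescaled by the age- and sex-specific conversion
factor

&nbsp;&nbsp;&nbsp;&nbsp;λ<sup>d</sup><sub>x</sub> = e<sub>x</sub> / e<sup>d</sup><sub>x</sub>,

the ratio of independent to dependent life expectancy at the conversion age
*x*. The retiree receives b·λ per year for an expected e<sup>d</sup> years
instead of b for e years — the expected payout, and hence the scheme's cost,
is unchanged. The package provides:

* **cohort life tables** by sex and health state (`life_table()`), with
  abridged-grid ingestion, survival probabilities, force of mortality and
  curtate/complete expectancies;
* **dependent-lives excess mortality**: multiplicative, additive and mixed
  logistic corrections (`apply_mixed()`, `derive_dependent_table()`), fitted
  Spanish severe/high-dependency presets (`excess_preset()`), and bounded
  least-squares parameter fitting (`fit_excess_params()`);
* **conversion schedules** (`build_schedule()`, `conversion_factor()`):
  per-age λ, relative excess mortality, sex differentials and expectancy
  gaps;
* a discrete annual **multistate model**
  (active/retired/dependent/disabled/dead) with closure validation and
  mass-conserving cohort projection (`project_cohort()`);
* **actuarial present values** (`pvfb()`) and the cost-free equivalence
  check (`check_equivalence()`), exact at zero interest;
* a **Gompertz–Makeham synthetic generator** and the printed 1970-cohort
  Spanish fixture (`fixture_table3()`) so everything runs offline.

## Worked example

Conversion schedule for men born in 1970, from the shipped printed fixture:

```r
library(ltcfactor)
sched <- build_schedule(fixture_slice("male", "independent"),
                        fixture_slice("male", "dependent"),
                        dep_other = fixture_slice("female", "dependent"),
                        sex = "male", cohort = 1970)
sched[sched$age %in% seq(65, 90, 5), ]
#> <conversion_schedule> male, cohort 1970, printed expectancies
#>  age lambda e_ind e_dep rel_excess abs_excess sex_diff  gap
#>   65  2.979  43.5  14.6      14.60    0.02409  0.53526 28.9
#>   70  3.353  38.9  11.6      21.27    0.05170  0.11673 27.3
#>   75  3.780  34.4   9.1      21.90    0.08195 -0.09038 25.3
#>   80  4.123  30.1   7.3      22.78    0.11941 -0.22880 22.8
#>   85  4.246  25.9   6.1      20.45    0.15764 -0.31376 19.8
#>   90  4.132  21.9   5.3      17.37    0.19048 -0.35859 16.6
```

Reading the age-65 row: a man becoming severely dependent at 65 has his
pension multiplied by λ ≈ 2.98 (expectancy falls from 43.5 to 14.6 years, a
gap of 28.9 expected payment-years); his dependent mortality rate is 15.6×
the general rate (`rel_excess` = q<sup>d</sup>/q − 1 = 14.60), and dependent
women of that age die at a 53.5% higher rate than dependent men
(`sex_diff`). λ peaks near age 85 and then declines as dependent and
general mortality converge at extreme ages.

The cost-free property, on synthetic schedules:

```r
pair <- make_dependent_pair(gm_params(), excess_preset("spain_severe_men"),
                            ages = 20:120)
lam <- conversion_factor(pair$independent, pair$dependent, 75,
                         "annuity_due", terminal_age = 121)
lam
#> [1] 3.02762
check_equivalence(pair$independent, pair$dependent,
                  pension_spec(12000, 65, 121), discount_curve(0), 75, lam)
#> [1] -2.11348e-16
converted_benefit(12000, lam)
#> [1] 36331.44
```

A 12,000/year pension becomes 36,331/year on dependency at 75, and the
equivalence residual between the two present values is zero to machine
precision: the conversion costs the scheme nothing.

See `vignettes/ltc-conversion-methods.Rmd` for the model, its assumptions,
and the numerical choices.

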