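---
title: "Methods: actuarial life tables, Leslie-matrix demography and the parametric bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actuarial life tables, Leslie-matrix demography and the parametric bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical methods implemented in `lifetab`:
the data model, the estimators, the Leslie-matrix analysis, the bootstrap,
and the design of the built-in simulator, including every numerical
convention a user might need to reproduce results exactly.

```{r setup}
library(lifetab)
```

# Data model

The unit of observation is an *individual-year*. A census study follows
individuals from an entry age (0 for those born in the study population,
positive for immigrants of estimated age) to an exit age, where the exit is
one of three fates:

* `death` — the individual was seen dead, or its permanent disappearance is
  demographically equivalent to death for its sex;
* `permanent_disappearance` — the individual left the monitored area and
  was never seen again (for a dispersing sex this usually *is not* death);
* `censored` — observation ended while the individual was alive (end of
  study, loss of the record, truncation of unreliable old ages).

Ages are whole-year age classes: an individual with `entry_age = 0` and
`exit_age = 3` was observed in classes 0, 1, 2 and 3 and left during class
3. Birth events carry the mother's id, her age class at the birth, and the
offspring's sex (possibly `unknown`, e.g. an infant that died before it
could be sexed). Each female-year can carry an *observation fraction* in
$[0, 1]$ — the share of that year she was actually monitored — which
weights the fertility estimator below.

`census_records()` validates a record set; `read_records()` /
`write_records()` move it to and from tab-separated text.

# Age-class counts and the at-risk recurrence

For one sex, `tabulate_counts()` reduces records to per-class counts: the
number entering the study in class $x$ ($t_x$), deaths ($d_x$), permanent
disappearances ($p_x$) and censorings ($c_x$). The number at risk in class
$x$ follows the recurrence

$$N_0 = t_0, \qquad N_x = N_{x-1} - dp_{x-1} - c_{x-1} + t_x,$$

where $dp_x$ pools deaths with permanent disappearances (see the policy
switch below). $N_x$ equals the direct count of individuals whose observed
span covers class $x$; the equality is exercised in the test suite.

# Actuarial mortality and survivorship

Individuals censored within class $x$ were at risk for only part of the
interval. The actuarial (half-interval) convention counts each of them as
half an individual at risk:

$$N_{q,x} = N_x - \tfrac{c_x}{2}, \qquad
  \hat q_x = \frac{dp_x}{N_{q,x}},$$

and survivorship to the start of class $x$ is the product-limit form

$$l_0 = 1, \qquad l_x = \prod_{i < x} (1 - \hat q_i).$$

With no censoring this reduces exactly to the Kaplan–Meier product-limit
estimator, which the test suite verifies against the independent
implementation in the `survival` package to $10^{-12}$.

Two conventions need to be made explicit:

* **Disappearance policy.** For a philopatric sex (often females in
  many mammal populations), permanent disappearance is treated as death
  (`disappearances = "deaths"`, the default). Treating disappearances as
  censoring (`disappearances = "censored"`) is available for sensitivity
  analysis but can badly underestimate mortality for a dispersing sex, and
  the function warns accordingly.
* **Truncation age $\omega$.** The table is truncated at the oldest class
  with an observed death (or pooled disappearance), because classes beyond
  the last death carry no mortality information. If survivorship reaches 0
  earlier, the table ends there. `estimate_life_table()` applies both
  rules.

A $\hat q_x > 1$ is impossible for a consistently tabulated count table;
the estimator still clamps to 1 with a warning as a guard for externally
assembled tables.

# Fertility

Female fertility is estimated per age class from observed births, weighted
by observation fractions. With $w_{f,x}$ the observation fraction of
female $f$ in class $x$ and $b_{f,x}$ her observed births,

$$\hat m_x = \frac{1}{2}\,
  \frac{\sum_f w_{f,x}\, b_{f,x}}{\sum_f w_{f,x}},$$

where the factor $\tfrac12$ converts births of all offspring (daughters
*and* sons, including unsexed newborns) to daughters per female under a
50:50 birth sex ratio. The empirical sex ratio itself is reported
separately by `sex_ratio()` with an exact (Clopper–Pearson) binomial
confidence interval, computed on sexed newborns only. The weight sums
$N_{m,x} = \sum_f w_{f,x}$ are the effective sample sizes carried into the
bootstrap.

A zero observation fraction removes a female-year from numerator and
denominator alike; unobserved births of partially observed females are
simply not in the data, and the weighting keeps the rate unbiased as long
as observation effort is unrelated to fertility.

`age_first_reproduction()` summarises the minimum observed birth age per
female (median and quartiles, type-7 quantiles), optionally restricted to
known-age females.

# Leslie matrix and derived statistics

For the female table truncated at $\omega$, the $(\omega+1) \times
(\omega+1)$ Leslie matrix has fertilities on the first row and survival
ratios on the subdiagonal:

$$A_{1,x+1} = m_x, \qquad A_{x+2,x+1} = \frac{l_{x+1}}{l_x}.$$

From the table and matrix, the package reports:

* net reproductive rate $R_0 = \sum_x l_x m_x$;
* generation time $G = \sum_x x\, l_x m_x / R_0$ (mean age of mothers at
  daughter production in the cohort schedule);
* asymptotic growth rate $\lambda$, the dominant eigenvalue of $A$;
* stable age distribution $w$ (dominant right eigenvector, scaled to sum
  to 1) and reproductive values $v$ (dominant left eigenvector, scaled to
  $v_0 = 1$);
* life expectancies $e_x$ from the fundamental matrix: with $U$ the
  survival part of $A$ (first row zeroed), $e$ is the vector of column
  sums of $(I - U)^{-1}$. This counts the current interval, so $e_x \ge 1$
  and $e_x = \sum_{y \ge x} l_y / l_x$; "additional expected years" is
  $e_x - 1$.
* survivorship to the median age at first reproduction,
  `survival_to_median_afr()`, by default $l_{\lfloor \tilde x \rfloor}$
  (with optional linear interpolation).

Under this matrix convention the dominant eigenvalue satisfies the
Euler–Lotka identity

$$\sum_x m_x l_x \lambda^{-(x+1)} = 1,$$

which the test suite checks to $10^{-9}$ across hundreds of random tables
(note the exponent $x+1$: row-1 fertilities act on individuals *entering*
class $x$ one projection step later).

**Eigen extraction.** `eigen_analysis()` takes all eigenvalues of maximum
modulus, picks the one with the largest real part, and verifies that it is
real and positive with a real eigenvector (Perron–Frobenius); residuals
$\lVert A w - \lambda w \rVert$ above $10^{-8}$ are an error rather than a
silent inaccuracy. Matrices with no positive fertility in the first row
($R_0 = 0$) are rejected, since no positive dominant eigenpair exists.

# Parametric bootstrap

Uncertainty intervals come from resampling the estimated schedules from
their sampling distributions (`bootstrap_ci()`):

* mortality: $q^*_x = X_x / n_x$ with
  $X_x \sim \mathrm{Binomial}(n_x, \hat q_x)$ and
  $n_x = \lceil N_{q,x} \rceil$;
* fertility: $m^*_x = Y_x / n_x$ with
  $Y_x \sim \mathrm{Poisson}(n_x \hat m_x)$ and
  $n_x = \lceil N_{m,x} \rceil$. (A single Poisson draw with mean
  $n_x \hat m_x$ is distributionally identical to the sum of $n_x$
  independent Poisson draws with mean $\hat m_x$, so the aggregated draw
  is used.)

Each replicate rebuilds $l^*$, $R_0^*$, $G^*$, the Leslie matrix (directly
from the resampled survival probabilities $1 - q^*$, so a mid-table
$q^* = 1$ cannot create a $0/0$ survival ratio), $\lambda^*$, $w^*$, $v^*$
and $e^*$. The truncation age $\omega$ is held fixed across replicates: it
is a structural choice of the table, not a sampled quantity. Replicates
with $R_0^* = 0$ leave $G$, $\lambda$, $w$ and $v$ undefined; they are
excluded from those percentile sets and their count is reported.

With the default `n_reps = 4999` replicates, the 95% interval is the
2.5th–97.5th percentile pair (type-7 quantiles) of the stored replicate
values. All replicates are stored in the returned object, so any other
functional of the bootstrap distribution can be computed afterwards.
Draws are ordered (age-ascending, mortality before fertility) so a seed
reproduces the envelope exactly.

Simulation experiments in the test suite confirm that the 95% interval
for $\lambda$ covers the generating value in roughly 95 of 100 simulated
studies of 1000 births.

# The simulator

`simulate_population()` exists so every estimator can be validated against
known truth. Design choices that matter for interpretation:

* **Calendar window.** The study runs for `study_years` calendar years
  (default: one more than the number of age classes). Each year,
  individuals present are exposed — in this order — to death
  ($q_x$), permanent disappearance, and censoring hazards; survivors of
  the final age class are censored there. The fixed window is what bounds
  recursive reproduction: daughters born during the study become study
  subjects and reproduce in turn, exactly as in a real multi-year census,
  without the unbounded growth a purely cohort-wise recursion would
  produce when $R_0 > 1$.
* **Births.** Each female present in class $x$ produces
  $\mathrm{Poisson}(2 m_x)$ offspring that year (both sexes; daughters
  with probability `sex_ratio_female`). If an observation-fraction law is
  configured, each birth is observed with the female-year's fraction;
  unobserved births leave no record, mirroring real monitoring gaps.
* **End-of-window censoring.** An individual alive at the end of the
  study has spent, on average, half of its current age class under
  observation. Rather than recording fractional exposure (which the
  age-class data model cannot represent), the simulator splits the
  boundary 50:50 at random: half exit censored at the last fully observed
  class, half are carried to the next class with an observation fraction
  of 0 for it. This makes the actuarial half-interval correction hold in
  expectation. The residual bias of the convention is below half a
  standard error at the sample sizes used in the tests.
* **Immigrants** enter at the start of a positive age class with full
  exposure from entry; `unsexed_infant_prob` optionally masks the sex of
  offspring that die in class 0, reproducing a common field limitation.

`true_life_table()` returns the generating schedule as a life-table object
so that estimates, and bootstrap coverage, can be compared against truth.
The packaged `reference_schedule()` is a 10-class schedule with infant
mortality, a senescent rise, a fatal terminal class (so complete cohorts
have a well-defined $\omega$) and a broad fertile plateau; its true
statistics are $\lambda \approx 1.0277$, $R_0 \approx 1.206$,
$G \approx 5.877$.

# Numerical conventions (summary)

* Quantiles: type 7 (R's default), both for age-at-first-reproduction
  summaries and bootstrap percentiles.
* Half-interval censoring correction: $N_{q,x} = N_x - c_x/2$; $\hat q_x$
  is `NA` where $N_{q,x} = 0$, and the survivorship product stops at the
  first `NA`.
* Bootstrap denominators are rounded *up* to whole individuals.
* $\omega$ fixed across bootstrap replicates.
* All delimited outputs are plain tab-separated text with `#` metadata
  lines; JSON summaries are written without digit truncation.

# Limitations

* No year effects or environmental covariates: hazards depend on age and
  sex only.
* Death and disappearance are independent competing hazards in the
  simulator; the estimator's `disappearances` policy is a binary choice,
  not a competing-risks decomposition.
* The actuarial correction assumes censoring is uniform within the age
  class; heavy, systematically early (or late) within-class censoring
  would bias $\hat q_x$.
* The fertility estimator assumes observation effort is independent of
  fertility, and the 50:50 halving assumes the birth sex ratio; use
  `sex_ratio()` to check the latter.

# A compact worked example

```{r example}
s <- reference_schedule()
cfg <- sim_config(true_q = s$q, true_m = s$m, n_births = 1000,
                  annual_censor_prob = 0.02, seed = 42)
rec <- simulate_population(cfg)
counts <- tabulate_counts(rec, sex = "F")
lt <- add_fertility(estimate_life_table(counts),
                    tabulate_fertility(rec, n_classes = counts$n_classes))
summ <- demographic_summary(lt, afr = age_first_reproduction(rec))
summ
env <- bootstrap_ci(lt, n_reps = 999, seed = 43)
env
```
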