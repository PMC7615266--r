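---
title: "Methods: quantifying educational inequalities in premature mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying educational inequalities in premature mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edumort)
```

# The scientific problem

Large prospective cohorts consistently show that adults with less schooling
die younger. Quantifying that inequality well requires several pieces of
methodology working together: rate ratios (RRs) that respect the cohort's
age structure, confidence intervals that allow any two education groups to
be compared (not only each group against the reference), a transparent
measure of how much of the association plausibly runs through lifestyle
and physiological mediators, and a way to translate *relative* study
effects into *absolute* national survival differences. `edumort`
implements that pipeline end to end, together with a synthetic-cohort
generator so that every stage is exercisable and testable without access
to restricted participant-level data.

# The survival model

## Age-at-risk stratification

Follow-up runs on the time-since-entry timescale. Each participant's
follow-up is split into 5-year *attained-age* bands ("Lexis expansion"):
a participant recruited at 48.3 who dies at 61.0 contributes records to
the 45–49, 50–54, 55–59 and 60–64 bands, with the death on the last
record. The premature-mortality window is ages 35–74 (deaths at 75+ are
censored at the 75th birthday); the same engine covers ages 75–84 by
configuration. Bands are half-open $[a, a+5)$; a death falling exactly on
a band edge belongs to the older band (this is measure-zero for
continuous ages, but the fitter handles the resulting degenerate record
so that constructed data cannot break it). Person-time and death counts
are conserved exactly by construction, and the test suite asserts this
identity on every simulated cohort.

The Cox model is stratified by these age bands and, in combined analyses,
by sex. Each stratum carries its own baseline hazard, so proportional
hazards is assumed only *within* strata — an important weakening for an
exposure like education whose RR may vary across the lifespan.

## Partial likelihood and its maximisation

Within stratum $s$, records are counting-process intervals
$(t_{start}, t_{stop}]$ with delayed entry; the risk set at an event time
$t$ is $\{i : t_{start,i} < t \le t_{stop,i}\}$. With Breslow handling of
ties, the log partial likelihood is

$$\ell(\beta) = \sum_s \sum_k \Big[ \sum_{i \in D_{sk}} x_i'\beta
  - d_{sk} \log \sum_{j \in R_{sk}} e^{x_j'\beta} \Big],$$

where $D_{sk}$ is the set of $d_{sk}$ deaths at the $k$-th event time of
stratum $s$ and $R_{sk}$ the risk set. Efron's correction is available as
an option; ties are rare on a continuous timescale and Breslow keeps the
independent test oracle (a direct per-event evaluation of the same
formula) simple.

Maximisation is Newton–Raphson with step-halving whenever a step fails to
increase the likelihood. Convergence requires a relative log-likelihood
change below $10^{-9}$ *and* a score max-norm below $10^{-6}$, within 50
iterations. The covariance matrix is the inverse observed information.
Risk-set sums are accumulated with difference arrays over the ordered
event times (each record contributes once at the first event time it
covers and is removed after the last), which makes the evaluation
$O((n + d)\,p^2)$ per iteration and keeps a 50 000-participant fit in the
low seconds. Strata without events contribute nothing to the likelihood
and are dropped with a log line. Apparent separation (a coefficient
drifting beyond $\pm 15$ on the log scale, i.e. RR beyond $e^{15}$) is
capped and flagged rather than left to wander.

Exposure levels enter as indicator contrasts against a chosen reference
(tertiary education in the headline analysis). The default model adjusts
for nothing beyond the stratification: age and sex are absorbed by the
strata, which matches an "adjusted for age and sex" reading of the
design; additional covariates can be supplied.

## Cause-specific mortality

Cause-specific analyses censor deaths from any other cause at the time of
death: `prepare_cause()` keeps the event flag only for the named cause
group (the registered vocabulary is `all`, `vascular` = cardiac + stroke,
and the component groups) and leaves person-time untouched, so summing
cause-specific death counts over the disjoint groups returns the
all-cause count exactly.

# Floated (group-specific) variances

Conventional output attaches a CI to each non-reference level and none to
the reference, and CIs for comparisons between two non-reference levels
cannot be read off. Floated variances repair this: each level $i$
(reference included) receives a variance $f_i \ge 0$ such that the
variance of any contrast $\log RR_i - \log RR_j$ is approximately
$f_i + f_j$.

Given the covariance matrix $V$ of the $K-1$ estimated contrasts, the
model variance of each pairwise contrast is $C_{0j} = V_{jj}$ (against
the reference) and $C_{ij} = V_{ii} + V_{jj} - 2V_{ij}$ otherwise. The
package solves the non-negative least-squares problem

$$\min_{f \ge 0} \sum_{i<j} (f_i + f_j - C_{ij})^2 ,$$

a transparent, testable construction that satisfies the floating
contract. Published floating-absolute-risk estimators exist in several
variants whose precise algebra differs; this least-squares formulation is
a deliberate methodological choice of this package, and the achieved
approximation error is never hidden: `max_contrast_distortion`, the
maximum relative error $|f_i + f_j - C_{ij}|/C_{ij}$ over all pairs, is
always reported (on realistic five-level education fits it stays below
5%, and this is asserted in the tests). Two structural facts make the
construction well-behaved: with a diagonal $V$ the exact solution
$f_0 = 0, f_i = V_{ii}$ is recovered with zero distortion, and with
$K = 2$ the single equation $f_0 + f_1 = V_{11}$ is under-determined, so
the minimum-norm tie-break splits the contrast variance equally — the
reconstructed contrast variance is exact either way.

# Mediation as proportional attenuation

The mediation measure is attenuation, not a counterfactual estimand: how
much does the education signal shrink when candidate mediators (smoking,
alcohol, physical activity as their category groupings; weight, height,
waist, hip and systolic blood pressure as linear terms; five-level
diabetes status) are added to the model?

Two statistics are computed on the identical record set (rows missing any
mediator are dropped from both nested models, a validity requirement for
likelihood-ratio comparisons):

* $\chi^2$ attenuation: with $\chi^2_{unadj}$ the LR statistic for adding
  education to the confounder-only model and $\chi^2_{adj}$ the same in
  the mediator-adjusted model, the proportion explained is
  $100(1 - \chi^2_{adj}/\chi^2_{unadj})$.
* log-RR attenuation, $100(1 - \log RR_{adj}/\log RR_{unadj})$, reported
  both for the headline none-versus-tertiary contrast and averaged over
  the non-reference levels, since a single published attenuation figure
  could summarise either; neither is privileged.

Percentages outside $[0, 100]$ are reported as computed — suppression
(negative attenuation) must remain visible. The statistic is calibrated
against its own generators in the tests: a generator whose education
effect runs entirely through included mediators drives the proportion
above 90%, and under a null exposure the LR statistic has mean
$\approx$ df. The two attenuation measures behave differently under a
*mediator-free* generator (mediators carry no hazard effect), and the
tests reflect this deliberately: the log-RR attenuation concentrates at
zero, because covariates without hazard effects leave the adjusted
estimand unchanged; the $\chi^2$ attenuation does *not* when the null
mediators remain education-graded — conditioning on exposure-correlated
covariates reduces the conditional information about the exposure, so a
small positive attenuation (the collinearity fraction, a few percent at
realistic gradients) is the correct expectation, not a bug. Only when
the mediators are also independent of education does the $\chi^2$
proportion concentrate at zero, and that is the scenario under which it
is asserted. Users should read small $\chi^2$ attenuations with this
collinearity floor in mind.

# Projection to absolute rates

Study RRs are relative; national life tables are absolute. For each sex
and 5-year age band with national annual death rate $A^*$, the anchor
rate $A$ solves

$$\textstyle\sum_k p_k\, r_k\, A = A^*, \qquad A = A^* / \sum_k p_k r_k,$$

where $p_k$ are the education prevalences and $r_k$ the RRs (reference
$r = 1$); the level-$k$ absolute rate is $r_k A$. The identity holds to
machine precision by construction and is asserted at $10^{-12}$.
Survival from 35 is the piecewise-exponential curve of these band rates,
and the partial (truncated) life expectancy over $[35, 70)$ integrates
each band exactly: $S(a)\,(1 - e^{-5\lambda})/\lambda$ per band, with
limit $5S(a)$ as $\lambda \to 0$. Distinct RR vectors can be supplied for
ages 35–59 and 60–69, mirroring the age-range-specific RRs such
projections typically use.

Two conventions for "life expectancy from 35" are supported and clearly
separated: the truncated expectancy over $[35, 70)$ (the headline
number), and an optional constant-hazard continuation of the final band
beyond 70 (`extrapolation_age`), reported alongside. No claim is made
that either reproduces any particular published life-expectancy figure;
the published analogues depend on an external national life table. An
optional parametric bootstrap (`project_gap_bootstrap()`) propagates the
RR sampling uncertainty into the gap — an extension, not part of the
deterministic headline projection.

Two prevalence subtleties deserve note. `calibrate_rates()` applies the
anchor formula with the prevalences exactly as given, accepting vectors
whose sum is within 0.02 of 1, because published prevalences rounded to
whole percentages (e.g. 7/16/24/27/25, summing to 0.99) are the natural
input and the weighted-average identity holds regardless. The *default*
prevalences of `project_education_survival()`, however, are renormalised
to sum exactly to 1 so that the structural invariant "all RRs equal to 1
reproduces the national survival curve" holds to machine precision.

One projection caveat: raising a single group's RR (others fixed) never
raises that group's life expectancy and, through the smaller anchor $A$,
can only raise everyone else's — this compensation property is asserted
on randomised inputs. The stronger statement that a componentwise-larger
RR vector can never benefit any non-reference group is *not* true in
general (raising other groups' RRs deflates $A$ enough to lower a given
group's absolute rate), and the package deliberately does not assert it.

# The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, at
the study's conditions:

* cohort composition: 33% men; entry ages truncated-normal (mean 50.7,
  SD 10.8 years) on $[35, 85)$; entry dates uniform over 1998–2004;
  administrative censoring on 2020-12-31;
* education by sex following the study distribution (7/16/24/27/25% of
  men and 13/21/29/25/12% of women from no education to tertiary,
  renormalised from rounded percentages);
* education-conditional mediators: Gaussian continuous mediators with
  education-specific means (systolic blood pressure, BMI, waist and HbA1c
  decline with education; gradients follow the study's baseline
  cross-tabulations qualitatively) and multinomial categorical mediators
  (smoking, alcohol, activity, diagnosed diabetes). Published three-way
  smoking/drinking tabulations are expanded to the five analysis
  categories by fixed within-current splits. Mediators are conditionally
  independent given education and sex: the dependence structure among
  mediators is not described by cross-tabulated summaries, so no joint
  structure is invented. Correlations beyond those induced by education
  (and the height–weight link through BMI) are therefore absent, which is
  a stated limitation of what passing tests can show about real data;
* mortality: piecewise-constant cause-specific baseline hazards on 5-year
  age bands (total hazard doubling per decade from 0.0015/yr for men and
  0.0010/yr for women at 35–39, split across eight cause groups in
  proportions mirroring the premature-death cause mix), multiplied by a
  direct education effect and log-linear mediator effects. Event times
  are drawn by exact inversion of the cumulative hazard — no discrete-time
  approximation, so parameter-recovery tests are not confounded by
  discretisation bias — and the cause is drawn proportional to the
  cause-specific hazard at the event age;
* reproducibility: all randomness flows from one root seed; draws are
  made in fixed vectorised blocks keyed by participant index, so row
  order never changes any participant's draws and identical
  configurations give byte-identical cohorts.

Scenario configurations used in the calibration tests fix the generative
truth: a direct-effects-only scenario with RRs (1.8, 1.75, 1.6, 1.35, 1)
for parameter recovery; a null scenario for LR calibration; and a
fully-mediated scenario in which education acts only through steepened
SBP and diabetes gradients. The mediation scenarios use SBP and diabetes
as the designed channels — a narrow channel set keeps the adjusted model
exactly specified, so the full-mediation limit is a property of the
statistic rather than of a fortunate functional form.

What the generator does **not** emulate: the full joint covariate
distribution (only education-conditional marginals), age-by-education
birth-cohort structure, migration or loss to follow-up (censoring is
purely administrative), and cause misclassification. Passing tests
demonstrate the pipeline's internal correctness and calibration under
the assumed model, not fidelity to any real cohort.

# Quality control conventions

Exclusions apply in a fixed sequential order — (1) entry age $\ge 85$,
(2) missing education, (3) missing or extreme covariates (height outside
120–200 cm, weight outside 35–250 kg, BMI outside 15–60 kg/m², waist
outside 60–180 cm, hip outside 70–180 cm, waist-to-hip ratio outside
0.5–1.5), (4) uncertain mortality linkage — each row excluded once, by
the first rule it violates, so the ledger counts read sequentially.
Category conventions: income bands are left-closed on their lower bounds
with "no income reported" kept as its own category (never imputed, since
it can reflect either high or low socioeconomic position; income analyses
are restricted to men via the pipeline's sex filter); deprivation-score
quintiles use linear-interpolation percentiles with boundary values
assigned to the lower quintile; undiagnosed diabetes requires HbA1c
strictly above 6.5% without a prior diagnosis, and undiagnosed
participants with missing HbA1c are retained with an explicit `unknown`
status. The five-level smoking variable is kept for modelling; how
occasional smokers fold into a three-way display is a presentation
question the pipeline leaves open.

# Problem sizes and numerical choices

The bundled demo and the acceptance script run at 20 000 participants;
calibration tests use 50 000 (single-cohort recovery), 200 replicates of
5 000 (CI coverage), 100 000 (mediation limits) and 200 replicates of
3 000 (null LR calibration) — sizes at which the asymptotic arguments the
checks rely on are comfortably in force while a full run stays at desk
scale. Key tolerances: Newton convergence as above; floated-variance
solutions validated against a grid-search oracle at $10^{-4}$; projection
identities at $10^{-12}$; closed-form survival quantities at $10^{-10}$;
the engine agrees with an independent brute-force maximiser at $10^{-6}$
on small instances and with `survival::coxph` (`timefix = FALSE`, since
times here are genuinely continuous) to near machine precision.

# Known limitations

Attenuation is not causal mediation; single-baseline mediator
measurements would understate mediation in real data; the floated
variances are a least-squares construction, not a re-derivation of any
specific published floating-absolute-risk estimator; the projection
assumes the study RRs transport to the national population and ignores
cause-mix differences; and the bundled life table is synthetic — supplied
for demonstration, clearly labelled, and not a source for real
national estimates.
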