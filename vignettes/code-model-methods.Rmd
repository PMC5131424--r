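---
title: "Methods: the CoDe mortality curve, its estimation, and the delay–compression decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CoDe mortality curve, its estimation, and the delay-compression decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codemort)
```

## The model and its assumptions

`codemort` models the single-year death probability $q(x)$ — the chance
that a person alive at exact age $x$ dies before $x+1$ — as the sum of five
additive components, each owning one stage of life:

$$
q(x) = \frac{A}{x+B}
 + \frac{a\,e^{x-16}}{1+e^{x-16}}
 + \mathbb{1}(x \le M-h)\,K_{b_1}(x)
 + \mathbb{1}(M-h < x \le M)\,[K_{b_2}(x) + c_1]
 + \mathbb{1}(x > M)\,[K_{b_3}(x) + c_2],
$$

where $K_b(x) = b\,e^{b(x-M)} / (1 + \tfrac{b}{g}e^{b(x-M)})$ is a
Kannisto-type logistic anchored on the modal age at death $M$, rising with
slope $b$ and levelling off at the asymptote $g$.

The component interpretation drives everything downstream:

* **$A/(x+B)$** captures infant mortality and its childhood decline with an
  inverse-age law. $A$ (dimensionless, $>0$) sets the level; $B$ (years,
  $>0$) tempers the rate of decline. $B$ has an order of magnitude less
  leverage on life expectancy than $A$ (compare
  `param_sensitivity(p, "A", 10)` with `param_sensitivity(p, "B", 10)`),
  which is why the decomposition treats it as a nuisance constant.
* **the hump/background logistic** rises steeply around age 16 (the
  "accident hump") and plateaus at $a$, the age-independent background
  (Makeham-type) mortality of adulthood. One parameter covers both
  features.
* **three adult logistics** share the location $M$ but have separate slopes
  below $M-h$ ($b_1$, young adulthood), between $M-h$ and $M$ ($b_2$, late
  adulthood), and above $M$ ($b_3$, old age). Because each regime is only a
  windowed piece of a logistic, the constants
  $c_1 = K_{b_1}(M-h) - K_{b_2}(M-h)$ and
  $c_2 = K_{b_2}(M) + c_1 - K_{b_3}(M)$ (closed forms; see
  `continuity_constants()`) keep the assembled curve continuous at the two
  breakpoints. When $b_1=b_2=b_3$ both constants vanish and the three terms
  collapse to a single logistic — the model nests the simpler
  shifting-logistic description.

Boundary membership is decided by real-valued comparison exactly as the
indicators are written: an age equal to $M-h$ belongs to the first regime,
an age equal to $M$ to the second. $M$ is continuous, so with integer age
grids the breakpoints generally fall between grid points.

Assumptions worth stating: mortality is a smooth function of age within
each regime (no cohort effects, no period shocks within a year); the
old-age rise decelerates toward a finite asymptote rather than growing
Gompertz-fashion without bound; and the time evolution of a population's
mortality is expressible through the five time-varying parameters ($A$,
$a$, $M$, $b_2$, $b_3$) with $B$, $b_1$ and the structural constants nearly
fixed.

## Structural constants

* `h = 30` years splits adulthood below the mode into a young-adult and a
  late-adult window; with modal ages near 80 the three regimes cover
  roughly ages up to 50, 50–80, and 80+. It is shared across populations
  and years so that slope estimates are comparable.
* `g = 0.7` is the death-probability ceiling implied by capping the death
  *rate* at 1 in a one-year interval with deaths halfway through
  ($q = 1/(1+0.5) \approx 0.67$, rounded to the conventional 0.7). It is a
  configuration knob (`fit_options(g = 0.5)`) so the flat-at-0.5
  alternative supported by supercentenarian data can be explored, but 0.7
  is the shipped default.
* `m_hump = 16` years centres the accident hump; adolescence excess
  mortality is well located there across the populations this model is
  aimed at.

These are defaults of `code_params()` and `fit_options()`, never
hard-coded: the decomposition refuses to compare parameter sets whose
structural constants differ.

## Life-table conventions

`life_table()` builds a standard single-year period table with radix 1, so
the deaths column $d(x)$ is directly the age-at-death distribution used in
the objective. The separation factor (average fraction of the interval
lived by those dying in it) is 0.5 at all ages except age 0, where deaths
concentrate early in the interval; the default `a_frac_infant = 0.14` is a
protocol constant, deliberately exposed as an argument because published
life-table protocols differ in their infant-separation rules and the exact
rule is external to the model.

Two closure policies exist. Observed schedules are closed by forcing
$q = 1$ at the last observed age (`"terminal-one"`), or left open
(`"none"`), in which case $\sum_x d(x)$ falls short of 1 by the recorded
survivorship beyond the last age. Model curves are closed by
`code_life_table()`: the fitted curve is evaluated to age 120 and
terminated there, far enough beyond observed data that closure artifacts
are negligible for any parameter set in the supported domain. All
decomposition quantities use this model-extended closure so that components
are never contaminated by end-of-data effects.

## Estimation

The model is fit to death probabilities, not rates: probabilities are what
life tables and projections consume, and the objective's distribution half
is only defined on the probability scale. Rate schedules are converted
first with the standard interval conversion
$q = m/(1+(1-a)\,m)$ (`mx_to_qx()`).

The criterion is the variance-weighted average of two mean squared errors
over the fit range (default ages 0–100):

$$\frac{1}{2}\left(
 \frac{\mathrm{MSE}[\log q]}{\mathrm{var}[\log q]} +
 \frac{\mathrm{MSE}[d]}{\mathrm{var}[d]}\right)
 = 1 - \tfrac{1}{2}(R^2_{\log q} + R^2_{d}).$$

The $\log q$ half is a relative-error criterion dominated by young ages;
the $d$ half weights absolute errors around the modal age. Variances are
population variances across ages of the *observed* series, computed once
and treated as fixed weights, which makes the objective identically
$1-\bar R^2$ — minimizing it maximizes average $R^2$, and `fit_objective()`
returns both forms.

Numerical choices:

* Both the observed and the model $d(x)$ entering the objective are the
  open-table deaths $d(x)=l(x)q(x)$ restricted to the fit ages. For ages
  inside the fit range this equals the model-extended closed table's
  deaths, and it makes the objective exactly zero when the model equals the
  data.
* Positive parameters are optimized on the log scale; $M$ on the natural
  scale. Box bounds (documented in `fit_options()`) keep the search in the
  demographically meaningful region.
* The local optimizer is `stats::nlminb` (bounded PORT quasi-Newton) run
  from `n_starts = 8` Latin-hypercube points in the transformed box plus
  one data-driven start (infant level from $q(0)$, background from adult
  $q$ around ages 25–35, $M$ from the adult mode of the observed $d$); the
  best local optimum is polished by restarting until stagnation. The whole
  procedure is deterministic given `seed`. PORT termination codes that
  report relative/X/singular convergence are treated as converged; only
  evaluation-limit hits and false convergence are flagged.
* Ages with observed $q = 0$ (possible in small populations) are excluded
  from the log-q half and retained in the d half by default
  (`zero_q_policy = "exclude"`); a floor policy is available instead. With
  large-population inputs the policy never triggers.
* `fit_series()` processes years in calendar order and, from the second
  year on, runs a warm start at the previous solution alongside the cold
  multi-start, keeping whichever scores better — the warm start can
  accelerate but never degrade a year. Per-year failures (e.g. an all-zero
  year) are caught and flagged without aborting the series.

The Siler comparison model $m(x) = a_1e^{-a_2x} + c + b\,e^{b(x-M)}$ is fit
with the same machinery; its rates are converted to probabilities before
scoring so the two models are compared on a common scale. Being
single-slope, it cannot express different compression below and above the
mode, which is the gap the three-slope curve exists to close — on data
generated with $b_2 > b_1$ its average $R^2$ is strictly lower, a property
the test suite checks.

## The decomposition

`decompose_e0()` attributes the change in model life expectancy at birth
between two fitted parameter sets to four components by sequential
substitution: starting from the first year's parameters, replace in order
the young-age group ($A$, $a$), the modal age $M$, the below-mode slopes
($b_1$, $b_2$), and the above-mode slope ($b_3$) with their end-year
values, building a model-extended life table at each step. Each component
is the $e_0$ difference between consecutive tables, so the four components
telescope exactly to the $e_0$ change between the chain's endpoints.

Three design points were genuinely open and decided as follows:

* **Substitution order.** Components are path dependent. The default order
  young → delay → middle → old follows the narrative sequence in which the
  effects are naturally presented (young-age decline first, then the shift,
  then the shape changes around the mode); an `average_orders = TRUE`
  option averages each component over all 24 permutations for users who
  prefer a path-free (Shapley-style) attribution, but it is off by default
  so that the default output corresponds to one interpretable chain.
* **$B$ is not a component.** It is empirically near-constant, has little
  $e_0$ leverage, and belongs to no life stage of the attribution. The
  substitution chain therefore ends at the end-year parameters with $B$
  held at its start value; when observed life expectancies are supplied,
  any drift in $B$ lands in the `unexplained` remainder together with the
  fit discrepancies of both years.
* **Pace of delay.** `delay_pace()` is ten times the least-squares slope of
  the fitted $M$ on calendar year (years per decade). A regression uses
  every year rather than only the endpoints, which matters once sampling
  noise is present.

`compression_gain()` quantifies shape change separately from shift: it
compares the fitted end-year distribution with the start-year distribution
*shifted* to the end-year modal age (`shift_only_distribution()`, which
changes $M$ and nothing else) and integrates the positive part of the
difference. "Around the modal age" is operationalized as exactly that
positive part — no fixed age window — because the positive excess of the
compressed distribution over the shifted one is concentrated near the mode
by construction, and a window would add an arbitrary tuning constant. The
total is split by substituting each shape group one at a time on top of the
shifted baseline; the three sources sum to the total up to an interaction
residual that is reported, not hidden. The gain is zero, to numerical
precision, whenever the end distribution is itself a pure shift — an
invariance the test suite checks over random parameter draws.

## The synthetic generator

`generate()` and `generate_series()` exist so that every operation is
testable against a known truth with no external data. They emulate:

* evaluation of the model curve on an integer age grid (the noise-free
  case is the model schedule exactly);
* finite-population sampling: deaths at each age drawn independently as
  $\mathrm{Binomial}(E, q(x))$ with exposure $E$ persons per age, giving
  the $1/\sqrt{E}$ fluctuation scale of unsmoothed observed schedules;
* secular trends: linear per-year drifts of any subset of parameters,
  validated each year.

The presets are package fixtures chosen once: `"early"` (high $A$ and $a$,
$M = 80$, slopes 0.10/0.10/0.11) resembles a mid-century schedule,
`"late"` (low $A$, $a$, $M = 90$, slopes 0.10/0.14/0.16) a recent one, and
`"equal_slopes"` exercises the collapse case. The young-adult slope is kept
near 0.10, its empirically stable value. Within each preset the slope gap
between $b_3$ and $b_2$ is kept moderate so that the adult mode of the
implied $d(x)$ sits within a year of the parameter $M$ — with a large gap
the discrete-table mode drifts a couple of years above $M$, which would
break $M$'s defining interpretation inside the fixtures themselves.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: overdispersed or age-correlated errors, cohort
effects, age heaping and other data artifacts, wars and epidemics, and any
mortality pattern outside the model family (recovery tests draw data from
the model itself, so they demonstrate identifiability and optimizer
correctness, not real-world goodness of fit). Real-data fit quality must be
judged by the reported $R^2$ pair when the package is applied to observed
schedules.

## Problem sizes and tolerances

The test suite and the acceptance script use ages 0–100 (fit range) with
life tables closed at 120; the serial experiments use 61 annual schedules
with binomial exposure $10^6$ per age, and smaller multi-year fixtures
where trends are not the point. Telescoping and shift-invariance are
asserted at $10^{-9}$ years; algebraic identities (collapse, continuity
constants, $R^2$ relation) at $10^{-12}$ or exactly; noise-free parameter
recovery at 0.5% relative (0.05 years on $M$) with objective below
$10^{-10}$; noisy modal-age recovery at half a year over ten replicate
draws. These reflect what the arithmetic and the optimizer deliver with
margin, not empirical claims.

## Known limitations

* Single-year period tables only; no abridged tables, no cohort surfaces,
  no cause-of-death structure.
* No standard errors or confidence intervals for fitted parameters; the
  criterion is a descriptive least-squares fit, not a likelihood.
* The fitter needs schedules spanning early childhood to at least age 90;
  adult-only data cannot identify the infant and hump terms.
* The decomposition is parametric: it attributes the *model's* life
  expectancy change, and the residual between model and observed life
  expectancies is reported as unexplained rather than distributed over
  components.
* HMD input support covers the 1×1 period layouts (and plain CSV); 5-year
  and cohort layouts are out of scope.
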