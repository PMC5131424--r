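# codemort

Delay and compression of mortality from the full age pattern of death
probabilities.

Post-war gains in life expectancy mix two distinct processes: **delay** — the
whole adult mortality schedule shifting to older ages, visible as a rising
modal age at death — and **compression** — the age-at-death distribution
changing shape as mortality falls faster at some ages than at others.
Compression below the modal age (fewer premature deaths) raises life
expectancy; compression above it (slower progress at the oldest ages) lowers
it. `codemort` is for demographers and mortality modellers who want to fit a
single parametric curve to single-year-of-age death probabilities over the
whole age range, track its interpretable parameters through time, and split
a change in life expectancy at birth into delay and stage-specific
compression components.

## The model

The CoDe ("compression and delay") curve describes the death probability at
age *x* as the sum of five additive components:

```
q(x) = A/(x + B)                                    infancy and childhood
     + a e^(x-16) / (1 + e^(x-16))                  accident hump + background
     + I(x ≤ M-h)      b1 e^(b1(x-M)) / (1 + (b1/g) e^(b1(x-M)))
     + I(M-h < x ≤ M) [b2 e^(b2(x-M)) / (1 + (b2/g) e^(b2(x-M))) + c1]
     + I(x > M)       [b3 e^(b3(x-M)) / (1 + (b3/g) e^(b3(x-M))) + c2]
```

The three adult terms are Kannisto-type logistics sharing the modal age at
death *M* as location parameter, with separate slopes in young adulthood
(`b1`, below `M−h`), late adulthood (`b2`), and old age (`b3`, above the
mode); `c1` and `c2` are closed-form offsets that keep the curve continuous
at `M−h` and `M`. The constants `h = 30` (window width), `g = 0.7` (old-age
asymptote of each logistic), and the hump centre 16 are structural defaults,
exposed for sensitivity analysis. Rising `M` means delay; rising `b2`
(resp. `b3`) means compression below (resp. above) the mode; falling `A` and
`a` mean fewer young-age deaths.

Parameters are estimated by minimizing the variance-weighted average of the
mean squared errors of `log q(x)` and of the age-at-death distribution
`d(x)`,

```
(MSE[log q]/var[log q] + MSE[d]/var[d]) / 2  =  1 − (R²_logq + R²_d)/2 ,
```

so the fit maximizes average R² over the log-probability and distribution
scales simultaneously. The five-parameter Siler curve is included as a
single-slope comparison model. Life tables use standard single-year period
conventions (radix 1, configurable infant separation factor, model-extended
closure at age 120), and the decomposition substitutes parameter groups —
young age (`A`, `a`), delay (`M`), middle age (`b1`, `b2`), old age (`b3`)
— sequentially between two fitted years, each component being the life
expectancy difference between consecutive substituted life tables.

## Worked example

Simulate a recent-period schedule with binomial sampling noise at one
million person-years of exposure per age, refit it, and decompose the life
expectancy gain since a mid-century baseline:

```r
library(codemort)

s <- generate(code_preset("late"), ages = 0:100, exposure = 1e6, seed = 42)
fit <- fit_code(s, fit_options(seed = 1))
glance(fit)
#> # A tibble: 1 × 7
#>   model objective r2_logq  r2_d r2_avg converged n_evals
#>   <chr>     <dbl>   <dbl> <dbl>  <dbl> <lgl>       <dbl>
#> 1 code   0.000136   1.000 1.000  1.000 TRUE          853

decompose_e0(code_preset("early"), fit$params)
#> <e0_decomposition>
#>   model e0: 63.604 -> 82.969 (change 19.365 years)
#>   delay of mortality (M):        +9.725
#>   young-age mortality (A, a):    +10.327
#>   middle-age mortality (b1, b2): -0.433
#>   above modal age (b3):          -0.255
```

The fit recovers the generating parameters (modal age 90.0, slopes 0.10 /
0.14 / 0.16) with both R² above 0.999. The decomposition reads: of the 19.4
years separating the two model life expectancies, 9.7 years come from the
modal age shifting 10 years later (delay), 10.3 from the collapse of infant
and background mortality, while the slope changes below and above the mode
cost −0.4 and −0.3 years (the steeper old-age slope concentrates deaths at
the mode but removes survivorship beyond it). `autoplot()` methods show the
fitted curves, and `compression_gain()` measures the extra share of deaths
near the mode relative to a pure shift.

A command-line wrapper with `simulate`, `fit`, `fit-series`, `lifetable`,
`decompose`, and `compare-models` subcommands is installed under
`inst/cli/codemort.R`.

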