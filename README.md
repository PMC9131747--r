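# lcscreen

A Markov cohort state-transition model for the cost-effectiveness of lung
cancer screening in a Chinese smoking population, comparing eight policies:
low-dose CT (LDCT) alone or with a plasma micro-RNA signature classifier
(MSC) as a triage test on LDCT-positive nodules, annually or once, at 20 or
30 pack-year eligibility. It is aimed at health-economic modellers who want
a scriptable, testable re-implementation of this class of screening model.

## The model in brief

Twelve health states — Normal, CIS, stages I–IV, a post-treatment
maintenance state per stage, Death — advance in 1-year cycles from entry
(ages 50–74) to age 79. For a strategy *s* versus comparator *c*,

ICER = (C_s − C_c) / (Q_s − Q_c),

with discounted cost C = screening + false-positive workup + diagnosis +
treatment-at-entry + 10%-of-treatment maintenance per year, and Q the
utility-weighted discounted life-years (discount rate 5%/year). Strategies
cheaper and more effective than the comparator are *dominant*; efficiency
frontiers drop strictly and extended-dominated options. Uncertainty is
handled by one-way (tornado) sweeps, 10,000-iteration probabilistic
sensitivity analysis with beta/gamma distributions, acceptability curves
(NMB > 0 counting), and bisection threshold search on test operating
characteristics. The complete published input table ships as a validated
JSON config; quantities the source used but never printed (eligible-smoker
fractions, clinical presentation stages, PSA standard errors) are clearly
labelled, overridable fixtures. See `vignette("lcscreen-methods")` for
assumptions, fixtures and verification scope.

## Worked example

```r
library(lcscreen)
p <- load_parameter_set()            # published base-case inputs
cache <- new.env(parent = emptyenv())
outs <- lapply(0:7, run_strategy, cohorts = cohorts_at_age(65),
               params = p, .cache = cache)
cea_table(outs, comparator_id = 0L)
```

```
 strategy cost_millions  ly_10k qaly_10k       icer        label
        0       300.715 74.2229  74.0432         NA   comparator
        1       295.833 74.1940  74.0150   17321.30 nondominated
        2       313.426 74.2308  74.0509  164316.61 nondominated
        3       297.623 74.1953  74.0162   11463.30 nondominated
        4       309.959 74.2008  74.0198  -39490.86    dominated
        5       297.010 74.1904  74.0113   11595.80 nondominated
        6       324.242 74.2036  74.0221 -111708.07    dominated
        7       298.984 74.1909  74.0116    5479.06 nondominated
```

80,000 people starting screening at 65: population cost in CNY millions,
life-years/QALYs in 10,000s. Strategy 2 (annual LDCT, 20 pack-years) gains
the most QALYs (74.0509 vs 74.0432 for the 2021-guideline comparator) at
CNY 164,317 per QALY gained — cost-effective under the 3× GDP threshold
(CNY 212,676) but, under this package's fixed-population comparison and
fixture eligibility fractions, not dominant as the source reports (the
vignette analyses why). Negative ICERs here flag *dominated* conjunctive
strategies (more cost, fewer QALYs): the published conjunctive
stage-at-detection profile is later-stage than LDCT's, which outweighs the
false-positive savings at default workup prices.

Threshold search, e.g. the LDCT specificity at which annual 20-pack-year
screening versus no screening hits 1× GDP per QALY:

```r
threshold_search("spec_ldct", target = p$wtp_gdp, bounds = c(0.65, 0.97),
  icer_fn = function(x)
    evaluate_pair(list(2L, "none"), cohorts_at_age(60, n_cohorts = 1),
                  param_set(p, "spec_ldct", x))$icer)$value
#> 0.7212  (base-case specificity 0.81 is comfortably above it)
```

Command line (base case, tornado, PSA, threshold, config validation):

```sh
Rscript -e 'lcscreen::lcs_main(commandArgs(TRUE))' run --out results --start-age 65
Rscript -e 'lcscreen::lcs_main(commandArgs(TRUE))' psa --out results --n-iter 10000 --seed 1
```

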