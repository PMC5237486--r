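---
title: "Modelling the supply-demand gap for altruistic sperm donation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the supply-demand gap for altruistic sperm donation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(donorgap)
```

## The model

Jurisdictions that prohibit payment for gametes must meet the demand for
donor insemination (DI) from unpaid, altruistic donors. `donorgap`
implements the two population-based, top-down models commonly used to ask
whether such a program is feasible, plus the machinery (scenario
configuration, sensitivity, stochastic uncertainty, break-even analysis)
needed to use them as a reusable policy tool.

**Supply** is a multiplicative funnel. Starting from a male population
base $N$ (census count of age-eligible men, default ages 21-40), an
ordered chain of proportions filters the pool:

$$ D = \mathrm{round}\!\left( N \prod_{i=1}^{k} p_i \right), \qquad
   S = D \times b, $$

where the $p_i$ are, in order, awareness of the donation program,
willingness to donate, presenting for screening, and passing the medical
screening process; $D$ is the whole-donor count and $b$ the
allowable-live-births policy cap (default 25, following US guidance) that
converts donors into donation-equivalents $S$.

**Demand** sums three recipient segments -- same-sex female couples,
single women, and heterosexual couples with male-factor infertility. Each
segment is its own product chain: a base unit count (a direct couple
count, or a population base thinned through a derivation chain such as
"39.3% of women aged 20-44 are single"), times ordered seeking rates,
times a recipient-eligibility fraction (default 98%). Per-segment demands
are integerized *before* summation, so the total is a sum of whole
requests. One requesting woman/couple consumes one donation-equivalent
("sample"); that unit convention is assumed throughout.

**Gap.** The signed gap is demand minus supply in donation units. The
whole-donor equivalent rounds a shortfall *up* (`ceiling(gap / b)`: whole
donors must fully cover demand) and a surplus *down*
(`floor(|gap| / b)`: only complete spare donors count). The asymmetric
rule is inferred from the published values themselves (251.64 prints as
252 required; 3,482.36 prints as 3,482 spare); it is the only observable
evidence on the question, and we adopt it as the convention.

## Numerical choices

* **Exact fractions.** Proportions are stored losslessly as exact
  rationals derived from their printed encoding (`"25%"`, `"0.013"`,
  `"1/78"`), never as binary floating point at parse time. The published
  tables are sensitive to this: $4{,}307{,}710 \times 0.55 =
  2{,}369{,}240.5$ exactly, and only exact arithmetic guarantees the
  half-way case is seen as such.
* **Rounding** is half-away-from-zero (the 2,369,241 cell above is the
  evidence; banker's rounding would print 2,369,240).
* **Integerize late.** Expected counts carry full precision through the
  funnel; only the displayed per-stage counts and the final donor count
  are integerized. Donors are whole people, so integerization *before*
  the capacity multiplication is mandatory: $3{,}797 \times 25 =
  94{,}925$, whereas the unrounded product gives 94,922.
* **Two encodings of medical eligibility.** The screening pass rate is
  quoted both as 1.3% (0.013) and as the rational 1/78
  ($\approx 1.282\%$). The packaged base scenario pins 0.013 and the best
  scenario pins 1/78, because the published supply table is reproducible
  only under that split (63 donors requires 0.013; 3,797 requires 1/78).
  Both encodings are first-class and interchangeable in configuration.
* **Break-even.** Donations are a monotone step function of any single
  supply proportion (the step comes from donor integerization), so
  `break_even_parameter()` binary-searches a grid (default step $10^{-4}$)
  for the smallest feasible value and reports the exact root of the
  continuous relaxation alongside. The relaxation is linear in the
  parameter, so its root is solved in closed form rather than by
  bisection -- equivalent, and exact.

## Scenario configuration

Scenarios live in a flat key/value text format (see `?scenario-config`)
with one `[scenario:NAME]` section per scenario and keys mirroring the
parameter-table row labels in snake_case. The dialect is purpose-built
rather than YAML/JSON because lossless fraction encoding is the contract:
a round-trip must return `"1/78"` as `"1/78"`, not `0.01282051...`.
Write-then-read is the identity, field for field, and validation is total
-- malformed input yields a diagnostic naming the line or key, never a
partially built scenario.

`paper_fixtures()` packages the three published scenario columns
(`base`, `best`, `worst`); the same text ships as
`inst/extdata/paper_scenarios.cfg`.

## Calibration of the same-sex base, and documented discrepancies

Several published numbers cannot be recomputed exactly from the published
parameters. The package's policy is to reproduce what is reproducible,
compute honestly what is not, and document the difference rather than
silently matching:

* **Same-sex couple base.** The source quotes "approximately 30,000"
  same-sex female couples and a 0.528%-of-women fraction (which gives
  29,399). Neither value reproduces the published demands 4,319 (base)
  and 7,198 (worst) after rounding. The integer bases that reproduce
  *both* cells form the interval 29,378-29,381 (verified by brute-force
  scan in the test suite); the fixtures pin the calibrated direct count
  29,380. The 0.528% route remains available through
  `same_sex_base_from_fraction()` -- with a warning, and with an explicit
  choice between reading the fraction as counting couples or women, which
  the source leaves ambiguous.
* **Worst-case demand rows.** The published 21,447 (single women) and
  3,767 (heterosexual couples) recompute to 21,444 and 3,766 from the
  printed parameters. The model reports its computed values; the
  published worst-case *total* 32,412 is used as a direct input where the
  worst-case gap is reproduced (32,412 - 1,575 = 30,837 → 1,234 donors).
* **Male-factor fraction.** The methods prose says 30% of infertility is
  male-factor; the parameter table says 24.0%, and only 24.0% reproduces
  the demand of 2,260. Fixtures use 24.0%; the inconsistency is recorded
  in the parameter's source note.
* **The 5:2:2 ratio.** Segment utilization ratios (lesbian couples :
  single women : heterosexual couples, from a Belgian clinic cohort)
  reportedly calibrate the single-women seeking rate to 0.06% and the
  heterosexual rate to 1.8%. The algebraic inversion implemented in
  `calibrate_rate_from_ratio()` instead yields ≈0.081% and ≈1.4%: the
  published calibration procedure is under-specified and cannot be
  reconciled. The utility performs the literal inversion and does not
  force agreement.
* **Demand as percent of base.** The published demand-fraction cells
  print 0.1% (base) and 0.58% (worst). No consistent rounding rule yields
  both (the base value is exactly 0.1413%); `format_demand_fraction()`
  uses two significant figures, giving 0.14% and 0.58%.

## Uncertainty

The deterministic funnel is the expectation of a **binomial thinning**
process: each man independently passes each gate, so the count surviving
stage $k$ is $X_k \sim \mathrm{Binomial}(X_{k-1}, p_k)$, and likewise for
each demand segment's chains. `stochastic_funnel()` simulates this with a
single seeded generator (the seed is a required argument and is logged in
the result), returning means, standard deviations and central 95%
intervals. By the law of total expectation $E[X_k] = N \prod_{i \le k}
p_i$, which the test suite checks to within three standard errors at
10,000 replicates. Replicate donor counts are integers by construction
and are *not* passed through the half-away rounding rule, so the Monte
Carlo mean targets the pre-rounding expectation (63.0003 in the base
scenario), not the reported 63 -- comparing it to the rounded figure
would manufacture a spurious "bias".

The thinning model is deliberately minimal: it is the unique probabilistic
model whose expectation is the deterministic funnel with independent
gates. It quantifies sampling variability only; it does not model
parameter uncertainty (no priors, no correlations between stages).

`one_way_sweep()` generalizes the three-column scenario contrast to an
arbitrary grid over any single parameter, re-running the full pipeline at
each point.

## The synthetic census generator

`generate_population()` emulates the age-by-sex census extract that real
analyses start from: a per-sex total allocated across 1-year age bands on
[0, 100) by one multinomial draw, exactly conserving the total, fully
determined by the seed. `paper_population()` confines the allocation to
the published age windows (males [21, 41), females [20, 45)) so that
`extract_base()` returns the published bases 4,307,710 and 5,567,965
exactly. Age intervals are half-open everywhere; "ages 21-40" is encoded
as [21, 41), including 40-year-olds, and `extract_base()` refuses
intervals that do not align with band boundaries rather than pro-rating.

What the generator does *not* emulate: real age structure (the
within-range allocation is uniform-multinomial), census sampling error,
ethnicity, geography, or any correlation between demographics and
willingness to donate. A green test against synthetic tables therefore
establishes the *accounting* (extraction, conservation, alignment), not
demographic realism; the model's population bases are always taken from
configuration, so the generator's internal age profile never affects
scenario results.

## Limitations

The models are deliberate simplifications, and the package inherits their
scope: no donation frequency or donor attrition over time, no sample-bank
inventory dynamics (the births cap is the only capacity concept), no
age-structure refinement of demand, no cross-border or known-donor
channels, no recruitment cost model, and no multi-year demand projection.
Whether the births cap is simultaneous or lifetime capacity is not
specified by the source; the model treats donations and live births as
interchangeable units, exactly as the published capacity table does.

## A worked example

```{r example}
fx <- paper_fixtures()
res <- run_scenario(fx$base)
res$gap
break_even_parameter(fx$base, "supply.awareness")
```
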