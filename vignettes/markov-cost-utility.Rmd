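---
title: "A Markov cost-utility model for metastasis-directed therapy in oligorecurrent prostate cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model for metastasis-directed therapy in oligorecurrent prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdtcea)
```

## The decision problem

Patients with oligorecurrent prostate cancer (a PSA relapse with at most
three metastases) can be managed three ways: metastasis-directed therapy
(MDT, by stereotactic body radiotherapy or surgery) followed by delayed
androgen-deprivation therapy (ADT), surveillance followed by delayed ADT,
or immediate palliative ADT. MDT postpones the start of ADT — in the
randomised evidence the median ADT-free survival was 21 months after MDT
versus 13 months under surveillance — and because the ADT-free state has
both a higher utility (0.92 vs 0.78) and lower monthly cost than life on
ADT, deferral may buy health at an acceptable price. `mdtcea` asks, from a
healthcare payer's perspective: is MDT cost-effective?

## Model structure

The model is a cohort Markov chain with four health states:

* **ADT-free** — after MDT or under surveillance, no palliative ADT yet;
* **ADT** — palliative ADT initiated (symptomatic, polymetastatic or local
  progression);
* **CRPC** — castration-resistant disease, with elevated cost and a
  disease-specific death risk;
* **Death** — absorbing, from any alive state.

Allowed transitions are ADT-free → ADT, ADT → CRPC, any alive state →
death, and the self-loops. MDT and surveillance cohorts enter in the
ADT-free state; the immediate-ADT cohort enters in the ADT state. The
horizon is 60 one-month cycles (five years — the trial's follow-up is too
short to support longer extrapolation) from a start age of 68, with costs
discounted at 3%/year and effects at 1.5%/year, the Belgian reference
rates. The willingness-to-pay threshold is €40,000/QALY.

### Transition probabilities

Disease transitions are supplied as interval probabilities over segments
that partition the horizon — six-month blocks for ADT-free → ADT,
mirroring how trial estimates are distributed over six-month periods —
and converted to monthly probabilities under a constant hazard within the
block, $p_{\text{cycle}} = 1-(1-p_{\text{int}})^{1/k}$. Where only a
median time-to-event $m$ is available the monthly probability solves
$(1-p)^m = 0.5$ (`prob_from_median()`); both conversions reproduce the
source summary exactly, and blocks derived from a median are constant, so
carrying the last observed block past the trial's follow-up is the
minimal-assumption extrapolation to five years.

Background mortality comes from a male life table (`age`, annual `qx`)
with the prostate-cancer fraction of deaths at each age removed
multiplicatively, $q_x^{adj} = q_x(1-f_{PCa})$, because prostate-cancer
death is modelled explicitly — and only — in the CRPC state, where it
combines with background death as independent competing risks,
$p_{death} = 1-(1-p_{bg})(1-p_{PCa})$. Within a cycle, death is applied
first and disease transitions act on the survivors (off-diagonal disease
entries scaled by $1-p_{death}$), the standard cohort-model convention
that guarantees row-stochastic matrices without silent renormalisation;
a row that would still exceed probability one raises an error. The cohort
ages continuously (`start_age + cycle/12`) with `qx` looked up by integer
age, matching the annual granularity of life tables.

### Rewards, half-cycle correction and events

State rewards use trapezoidal (half-cycle-corrected) membership — the
mean of cycle-start and cycle-end occupancy — and discount factors
evaluated at cycle midpoints, $(1+r)^{-(t+0.5)/12}$, which is the
self-consistent pairing. Per-state monthly costs cover follow-up, the ADT
drug (the least expensive listed Belgian option, €63.4/month of a
€63.4–141.5 range) while on ADT, and the CRPC state's management;
grade ≥ 2 toxicity management enters as probability × intervention-rate ×
cost, per MDT treatment episode for MDT toxicities and per month on
ADT/CRPC for ADT toxicities (grade 1 events carry no economic weight).

One-off costs — the first MDT month (work-up plus the SBRT/surgery course
mixed by the trial's 25:6 usage ratio), ADT initiation, repeat MDT
rounds — attach to the transition *flows* of the cycle in which they
occur and are discounted at that cycle's midpoint, undiluted by
trapezoidal averaging: event costs are paid once, by the people flowing
through the event, and flow-attached booking is exact for that. Repeat
MDT, for which the source states only that multiple rounds occurred, is
encoded as a constant monthly probability of a repeat course while
ADT-free under MDT — the minimal mechanism consistent with the statement,
and a preset slot.

## Uncertainty analysis

The PSA varies every parameter of `param_table()` simultaneously: costs
are gamma distributed and probabilities/utilities beta distributed, both
moment-matched so each distribution has exactly the deterministic value
as mean and the stated standard error (`moment_match()`). Where a
standard error is not reported the default is 10% of the mean. Each of
the 10,000 base-case iterations enforces the ordering constraint by
capping each sampled utility at the sampled utility of the less
progressed state; parameters are drawn independently (no correlation
structure is described by the evidence). Verdicts per iteration use the
incremental net monetary benefit, $\lambda \Delta Q - \Delta C > 0$,
which agrees with the ICER rule in all four quadrants; the multi-strategy
acceptability curve assigns each iteration to the strategy with maximal
NMB (ties to the first strategy in the fixed order), so the curves
partition probability one.

Two "mean ICER" estimators are reported side by side, because the term is
ambiguous: the ratio of mean increments and the mean of per-iteration
ratios restricted to the north-east quadrant. They answer different
questions and can differ materially when the cloud straddles quadrants.

The scenario analyses are deterministic except the last: a tornado
analysis at 80%/120% of each parameter (values that would leave their
natural bound, e.g. a utility of 0.92 × 1.2, are clamped to the bound and
flagged rather than dropped); a bisection search, cross-checked against
the affine closed form, for the largest first-month-MDT or SBRT cost that
stays cost-effective at €40,000/QALY, to €1 precision; an effect-scaling
scan that interpolates the MDT arm's ADT-free → ADT block probabilities
linearly towards surveillance's ($p(s) = p_{surv} - s(p_{surv}-p_{mdt})$;
a log-hazard-scale alternative is available via `scale_on = "hazard"`
since the evidence does not state the scale); and a re-run of the PSA at
standard errors 0.05–0.25, read as absolute for utilities and
probabilities and relative for costs.

## The synthetic presets, and what a green test establishes

`make_paramset("stomp_base")` encodes every quantity the published
summary states: the 21/13-month medians, utilities 0.92/0.78, 3%/1.5%
discounting, age 68, 60 cycles, €40,000/QALY, the €63.4/month ADT drug,
and the 25:6 SBRT:surgery ratio. Quantities that exist only in the
source's appendix tables — the ADT → CRPC and CRPC-death probabilities,
per-state costs, event costs, the toxicity list, the repeat-MDT rate and
the per-parameter standard errors — ship as **flagged placeholders**
(`spec$placeholders`), chosen once as realistic 2018 Belgian magnitudes
(e.g. ~28-month median to castration resistance on palliative ADT,
~24-month median CRPC survival, €2,400/month CRPC management including
systemic therapy, €4,500 SBRT course) such that the deterministic base
case has the published qualitative structure: MDT is a north-east
trade-off versus surveillance and dominates immediate ADT. The loader and
the report functions warn while placeholders are active.

Consequently the test suite asserts two different kinds of statement.
Structural properties hold unconditionally: row-stochasticity and mass
conservation, agreement with a matrix-power closed form and with a
10⁶-path micro-simulation, the annuity and geometric-decay limits to
1e-10, moment recovery of the PSA distributions, NMB/ICER verdict
consistency, €1 agreement of bisection and closed-form thresholds, PSA
collapse as SE → 0, and bit-exact identity of the unit effect scale.
Published *numerical* outputs (total discounted costs of €17,088/€15,673,
the €8,136 and €7,435 cost ceilings, the 60% effect floor), by contrast,
depend on the appendix values and are reproduced only once those are
transcribed into the preset; with placeholders active the pipeline
produces the same tables and figures with the same structure but
different numbers, and no test pretends otherwise.

The synthetic world also simplifies reality in ways a user should know:
no correlation between parameters, no patient-level heterogeneity (the
micro-simulation exists as a validation oracle, not as the estimator),
toxicities as expected costs rather than stochastic events, and a life
table that is Gompertz-smooth rather than empirical.

## Numerical choices and edge cases

* Probability/utility draws and perturbations never leave `[0,1]`: the
  beta family is bounded, tornado ends are clamped, and the utility cap
  is applied after sampling.
* An ICER with zero QALY difference is reported as undefined (`NA`),
  never ±Inf; classification then falls back to the cost sign.
* South-west trade-offs (cheaper, less effective) count as cost-effective
  when the ICER exceeds the threshold — the NMB-consistent convention;
  the base case never enters this quadrant.
* Competing probabilities that would exceed one from any state raise an
  error rather than being renormalised.
* The bisection bracket doubles from twice the first-month MDT cost until
  the verdict flips, then halves to a €0.5 bracket; "no feasible
  threshold" is reported when even a zero cost is not cost-effective.
* Beta standard errors at or beyond the feasibility bound
  $\sqrt{m(1-m)}$ are rejected in user input, and truncated to 95% of the
  bound when a blanket scenario SE is applied to all parameters.

## A worked run

```{r basecase}
spec <- make_paramset("stomp_base", quiet = TRUE)
outcomes <- run_all_strategies(spec)
icer_table(outcomes, spec$wtp)[1:2, ]
```

```{r psa, eval = FALSE}
draws <- run_psa(spec, n = 10000, seed = 1)
psa_summary(draws, c("MDT", "SURVEILLANCE"))
multi_ceac(draws)
one_way_tornado(spec)
cost_threshold_search(spec, "first_month_mdt")
effect_scaling_scan(spec)
```

## Known limitations

Beyond the placeholder dependence discussed above: the five-year horizon
truncates both the costs and the benefits of deferring ADT; the
extrapolation carries the last trial block forward rather than fitting a
parametric survival model; health-state utilities come from literature,
not from trial-collected quality-of-life data; CRPC treatment toxicity
costs are excluded by design, which biases against finding MDT even more
favourable; and the model is programmed for exactly the four-state,
three-strategy structure — adding lines of therapy would require new
states, not new parameters.
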