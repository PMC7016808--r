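# mdtcea

A trial-based Markov cost-utility model for **metastasis-directed therapy
(MDT) in oligorecurrent prostate cancer**, from a healthcare payer's
perspective. The package is for health economists and clinical researchers
who want a tested, scriptable re-implementation of the full analysis —
deterministic base case, probabilistic sensitivity analysis (PSA),
acceptability curves and scenario analyses — rather than a spreadsheet.

## The model

Three strategies are compared over a five-year horizon in one-month cycles:
MDT followed by delayed androgen-deprivation therapy (ADT), surveillance
followed by delayed ADT, and immediate ADT. The cohort moves through four
health states — ADT-free, ADT, castration-resistant disease (CRPC), death —
with half-cycle-corrected rewards and differential discounting (costs
3%/year, effects 1.5%/year). The headline statistic is the incremental
cost-effectiveness ratio against a €40,000/QALY willingness-to-pay (WTP)
threshold:

```
ICER = (COST_mdt − COST_comparator) / (QALY_mdt − QALY_comparator)
```

Monthly disease transitions derive from interval probabilities or survival
medians under a constant hazard, `p = 1 − 0.5^(1/median)`; background
mortality comes from a male life table with the prostate-cancer fraction of
deaths removed, since prostate-cancer death is modelled only in the CRPC
state. The PSA samples costs from moment-matched gamma distributions and
probabilities/utilities from beta distributions, with the sampled utilities
capped so a more progressed state never scores higher.

Quantities published only in the source appendix (per-state costs, toxicity
and progression probabilities, standard errors) ship as **flagged
placeholder values** (`spec$placeholders`); the numbers below therefore
illustrate the pipeline on the preset, and become the published analysis
once the appendix tables are transcribed. See the methods vignette
(`vignettes/markov-cost-utility.Rmd`) for the full account.

## Worked example

```r
library(mdtcea)
spec <- make_paramset("stomp_base", quiet = TRUE)  # base-case preset
out <- run_all_strategies(spec)
out$MDT
#> <mdt_outcome> MDT: discounted cost €29941, 3.537 QALYs (undiscounted €32196, 3.658)
compute_icer(out$MDT, out$SURVEILLANCE)
#> <mdt_icer> MDT vs SURVEILLANCE: Δcost €2785, ΔQALY 0.198, ICER €14085/QALY [tradeoff_NE]
compute_icer(out$MDT, out$IMMEDIATE_ADT)
#> <mdt_icer> MDT vs IMMEDIATE_ADT: Δcost €-9356, ΔQALY 0.805, ICER €-11628/QALY [dominant]

draws <- run_psa(spec, n = 2000, seed = 1)
psa_summary(draws, c("MDT", "SURVEILLANCE"))
#> <mdt_psa_summary> MDT vs SURVEILLANCE (2000 iterations)
#>   mean Δcost €2803, mean ΔQALY 0.207
#>   ICER (ratio of means) €13537/QALY; NE-quadrant mean €16871/QALY
#>   P(cost-effective at €40,000): 95.2%; dominant in 2.5%
```

Reading this: MDT buys 0.198 extra quality-adjusted life years per patient
for €2,785 more than surveillance — €14,085 per QALY, well under the €40,000
threshold — and is *dominant* (cheaper **and** more effective) over
immediate ADT. The PSA says the surveillance comparison survives parameter
uncertainty in ~95% of iterations.

Scenario analyses: `one_way_tornado()` (80%/120% one-way sweeps),
`cost_threshold_search()` (largest first-month-MDT or SBRT cost that stays
cost-effective, by bisection with a closed-form cross-check),
`effect_scaling_scan()` (how much of the trial's ADT-deferral effect is
needed), `se_scenario_scan()` (PSA stability across SE magnitudes 0.05–0.25).
Report functions (`run_basecase_report()`, `run_psa_report()`,
`run_scenario_report()`) write the CSV tables; a thin CLI wrapper lives at
`inst/scripts/mdtcea.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the installed package end to end — deterministic base case, a
seeded PSA, the tornado, cost-threshold and effect-scaling scenarios —
logging the headline figures as it goes, and writes the JSON report to
`--out`.
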