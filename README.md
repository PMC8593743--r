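# psorpath

Markov cohort cost-utility modelling of sequenced biologic therapy for severe
chronic plaque psoriasis, from the Australian health-system perspective.

## The problem

Eight outpatient biologics are PBS-subsidised for severe plaque psoriasis.
The PBS review rules make therapy a *pathway*, not a single drug: a 12-week
induction, then 24-week maintenance periods, each ending in a PASI75 response
review; non-responders switch to a second and third biologic and finally to
best supportive care (cyclosporine + calcipotriol/betamethasone foam). This
package evaluates the eight pathways (one per first-line biologic) over a
96-week horizon — eight 12-week Markov cycles with half-cycle-corrected
accrual — and asks which first-line choice is cost-effective.

For each pathway the model accrues total cost (2020 AUD) and QALYs
(responders earn the controlled-psoriasis utility 0.89/year; induction,
failure and BSC earn 0.64/year), classifies the strategies by strict and
extended dominance, and reports incremental cost-utility ratios
ICUR = ΔC/ΔQALY against the least-cost pathway. One-way (tornado) and
probabilistic sensitivity analyses (Beta efficacy/utility draws, Gamma BSC
costs, 10,000 iterations, cost-effectiveness acceptability curves over
willingness-to-pay 0–100k AUD/QALY) quantify uncertainty. An exhaustive
pathway-enumeration oracle verifies the cohort engine on every scenario the
property tests generate.

## Worked example

```r
library(psorpath)

config <- builtin_base_case()        # bundled Australian 2020 scenario
arms   <- evaluate_all_arms(config)  # all eight pathways
classify_strategies(arms)
```

```
       strategy  cost  qaly             status icur_vs_reference icur_vs_next_on_frontier
1 tildrakizumab 40241 1.568           frontier                NA                       NA
2    adalimumab 42725 1.554 strictly_dominated           -174490                       NA
3   secukinumab 43012 1.582           frontier            194871                   194871
4   ustekinumab 45254 1.558 strictly_dominated           -494052                       NA
5    etanercept 45937 1.538 strictly_dominated           -193128                       NA
6    ixekizumab 48752 1.581 strictly_dominated            659762                       NA
7  risankizumab 49135 1.587           frontier            466179                  1260047
8    guselkumab 50032 1.584 strictly_dominated            607777                       NA
```

The tildrakizumab-first pathway is the cheapest (AUD 40,241; 1.568 QALYs) and
anchors the cost-utility frontier; secukinumab- and risankizumab-first buy
additional QALYs at roughly AUD 195k and 466k per QALY — far above customary
willingness-to-pay — while the other five pathways are dominated. A
probabilistic run reproduces the same ordering:

```r
psa <- run_psa(config, n_iterations = 10000, seed = 20200918)
psa$ceac[psa$ceac$wtp == 50000, c("wtp", "tildrakizumab", "secukinumab")]
#>      wtp tildrakizumab secukinumab
#> 51 50000        0.9268      0.0512
```

The `analysis/` scripts run the three full analyses and write their tables
under `results/`:

```sh
Rscript analysis/01_base_case.R   # arm_results.csv (+ alternative sequencing)
Rscript analysis/02_owsa.R        # tornado.csv, owsa_ranges.csv
Rscript analysis/03_psa.R         # psa_summary.csv, ceac.csv
```

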