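---
title: "The sequenced-biologic cost-utility model: structure, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sequenced-biologic cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psorpath)
```

## The decision problem

Adults with severe chronic plaque psoriasis who qualify for subsidised
biologic therapy under the Australian Pharmaceutical Benefits Scheme (PBS)
face a choice among eight outpatient biologics. The PBS shapes the clinical
pathway: each drug begins with a 12-week induction period and is continued in
24-week maintenance blocks, with a dermatologist review of PASI75 response
(a 75% improvement from the baseline Psoriasis Area and Severity Index) at
the end of every period. Non-responders switch drugs; after three failed
biologics they move to best supportive care (BSC, cyclosporine plus a
calcipotriol/betamethasone foam spray), which we treat as absorbing.

`psorpath` evaluates the eight *pathways* (first-line drug plus the fixed
later-line sequence) as a Markov cohort model over 96 weeks — eight 12-week
cycles — accruing health-system costs in 2020 AUD and quality-adjusted life
years (QALYs). No discounting is applied by default given the sub-two-year
horizon (`timeline(annual_discount_rate = )` exposes it).

## Model structure

States follow the pathway position: *induction* on line $\ell$ (one cycle),
*maintenance responder* on line $\ell$, and *BSC*. At an induction review a
fraction $p^{ind}_\ell$ becomes maintenance responders and the rest start the
next line's induction; at each maintenance review a fraction $p^{maint}_\ell$
remains (the same probability at every review — long-term trial data are too
sparse to support anything richer); the rest switch. Responders in
maintenance earn the controlled-psoriasis utility (0.89/year, PASI 4.1);
everyone else — induction, post-failure, BSC — earns the uncontrolled
utility (0.64/year, PASI 16.5). Mortality is not modelled: psoriasis does
not measurably affect it over this horizon, and no death state exists.

Review times are line-relative: a line starting at week $s$ is reviewed at
$s+12$, $s+36$, $s+60$, ... Because induction takes one cycle and
maintenance periods two, every transition falls on a cycle boundary.

## Reward accrual: the half-cycle convention

Treatment failure is not observed at the moment it happens; on average a
failing patient loses response halfway through a cycle. We implement this
with the classic half-cycle correction, stated here precisely because it is
the part of any cohort model that published summaries leave under-specified:

* Rewards (both utilities **and** costs) are attached to cycle-boundary
  states, with trapezoid weights $\tfrac12, 1, \dots, 1, \tfrac12$ over the
  nine boundaries of the eight-cycle horizon. Each boundary carries the
  state *after* any review at that instant. This is equivalent to assuming
  every transition occurs mid-cycle.
* The review falling exactly at the 96-week horizon **is** applied: it
  determines the state earning the terminal half-cycle reward (a responder
  failing the week-96 review contributes half a cycle of uncontrolled rather
  than controlled utility).
* A patient failing at the horizon accrues the *incumbent* line's drug and
  monitoring cost through the terminal half cycle: no new treatment line is
  initiated inside it.

All three choices are explicit and switchable in `reward_convention()`
(`accrual`, `horizon_review`, `terminal_cost`), with `cycle_start` and
`cycle_end` membership accrual available for comparison. The default was
selected by calibration against the published base-case table: with it, all
eight pathway QALY totals agree with the reference values to within 0.0004
(their printed rounding) and all eight cost totals to within 0.9%; the
`cycle_start`/`cycle_end` variants miss the QALY totals by an order of
magnitude more. We regard this agreement as identifying the convention the
original decision-model implementation used, not as a tunable fit: it is a single
discrete modelling choice, applied uniformly to every arm and every analysis.

## Drug acquisition costs and dosing

Table-level drug prices are *per PBS dispense of the maximum quantity*, net
of the AUD 41.00 patient co-payment. For most of the drugs one dispense is
one dose; for the frequently-dosed drugs it is not, and the dispensed prices
identify the pack sizes (2 x 40 mg adalimumab syringes, 4 x 50 mg etanercept
pens, 2 x 80 mg ixekizumab pens). `drug_profile()` therefore carries
`doses_per_dispense`, and dose calendars carry per-dose unit weights so that
the 80 mg adalimumab and 160 mg ixekizumab week-0 loading doses consume two
units. Dose calendars restart at week 0 whenever a new line begins (each PBS
drug starts with its own induction regimen), and a dose falling exactly on a
review boundary belongs to the following period (half-open interval
convention) — which makes ixekizumab's week-12 dose its first maintenance
dose.

Monitoring adds AUD 851 per induction period (dermatologist visits plus
baseline investigations) and AUD 155 per 24-week maintenance period,
pro-rated per cycle. BSC accrues the induction-level cyclosporine and foam
cost over its first cycle, maintenance-level costs per 24 weeks thereafter,
and maintenance-rate monitoring throughout (cyclosporine requires ongoing
specialist review; charging induction-level monitoring at BSC entry instead
changes no conclusion and is not done).

## Verification: the pathway-enumeration oracle

`enumerate_pathways()` exhaustively expands every root-to-leaf sequence of
review outcomes (25-41 pathways per arm at this horizon), computing each
pathway's probability as the product of branch probabilities and its rewards
by an independent per-pathway walk over the same accrual rules. The
probability-weighted sums must equal the cohort engine's totals; the test
suite enforces this to 1e-8 on the base case, across all reward conventions,
and on 100 randomly generated scenarios, alongside cohort mass conservation
at every boundary and the closed-form degenerate scenarios (flat utilities,
zero efficacy, perfect efficacy). The same compiled pathway basis powers the
probabilistic sensitivity analysis, so the oracle equivalence also validates
the PSA evaluation path.

## Sensitivity analyses

**One-way (tornado).** Each drug's induction and maintenance PASI75
probability is varied over its 95% CI; the two utilities and the four BSC
cost components are varied by ±20% (costs of the biologics themselves are
PBS-listed and therefore known, not varied). The controlled utility's upper
bound, 0.89 × 1.2 = 1.068, is deliberately **not** clamped at 1.0: the
published risankizumab ICUR range is reproduced exactly by the unclamped
bound (479,834 × 0.25/0.428 = 280,277), so clamping would misrepresent the
reference analysis. `owsa_parameters(clamp_utilities = TRUE)` restores the
cap for users who prefer utilities bounded by perfect health.

**Probabilistic.** 10,000 iterations sample all parameters independently:
Beta distributions for efficacies (method of moments from the CI,
$se = (hi-lo)/3.92$), Beta from mean/SD for utilities, and Gamma
distributions for the BSC cost components with a default coefficient of
variation of 0.2, mirroring the ±20% one-way convention since no spread is
published. Probabilistic ICURs are ratios of iteration-averaged increments
(means first, ratio second). The cost-effectiveness acceptability curve
records, per willingness-to-pay value on a 0-100,000 AUD grid (step 1,000),
the fraction of iterations in which each arm maximises net monetary benefit
$\mathrm{NMB} = \lambda \cdot \mathrm{QALY} - \mathrm{cost}$.

The uncontrolled-psoriasis utility is printed as mean 0.64, SD 0.49 — no
Beta distribution has these moments (the feasible maximum SD is ~0.48).
`beta_from_mean_sd()` offers both fallbacks; the PSA default holds the
parameter fixed (`point_mass`). The choice is consequential: a
clamped, near-maximal-variance Beta makes the utility gap between the two
health states change sign in a third of draws and drags the tildrakizumab
acceptability at WTP 50,000 to ~81%, whereas holding the parameter fixed
reproduces the published ~90% and the published probabilistic ICURs to
within ~2%. We conclude the reference analysis effectively did not sample
this parameter, and adopt that as the default while documenting both modes.

## Synthetic scenarios

`generate_scenario()` produces random, structurally valid scenarios —
probabilities with proper CIs in (0,1), positive costs, ordered utilities,
dosing patterns cycling through the PBS menu (front-loaded, weekly, q2w,
q4w, q8w, q12w) — under a fixed seed, so that every pipeline stage is
property-testable without external data. It emulates the *shape* of the
inputs, not their joint realism: costs and efficacies are sampled
independently and uniformly, so synthetic scenarios say nothing about which
real drug is cost-effective. Passing the property suite on them demonstrates
the model machinery (mass conservation, oracle equivalence, dominance
classification) is correct, not that any clinical conclusion generalises.
There is no patient-level simulator because the model has no patient-level
inputs.

## Numerical choices and problem sizes

Everything is double precision; cohort fractions are checked to sum to 1
within 1e-9 per boundary. Dominance classification sorts by cost with ties
broken by QALY then name; exact cost-and-QALY ties are both kept on the
frontier. ICURs with zero QALY difference are reported as undefined (`NA`),
never infinity. The PSA evaluates arms through the compiled pathway basis
(probabilities via exponent matrices in log space), which makes 10,000
iterations x 8 arms a few seconds of work; the test suite runs in under a
minute with the full 10,000-iteration PSA and a 100-scenario oracle sweep.
The analysis scripts use 10,000 iterations (seed 20200918) and the default
44-evaluation tornado.

## Known limitations

* Maintenance response probabilities are constant across reviews; real drug
  survival declines over time and differs by class. Over 96 weeks this is
  the published model's own simplification; over longer horizons it would
  not be credible.
* The two arms whose third line is guselkumab (risankizumab- and
  ixekizumab-first) come out ~AUD 300 cheaper here than in the reference
  table (0.6% of the arm total, within the 2% reproduction band but visible
  in their ICURs, which sit ~2-3% below the published values). The pattern
  resists every mechanistic explanation we tested and is most plausibly
  rounding of the reference analysis's unpublished internal inputs.
* No adverse-event costs, no weight-band dosing beyond the 85 kg ustekinumab
  assumption, no patient heterogeneity, no correlation structure in the PSA
  (none is published).
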