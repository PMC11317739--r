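---
title: "Methods: meta-analysis and lifetime cost-minimization model for AF ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis and lifetime cost-minimization model for AF ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afablcma)
```

# Scope and rationale

`afablcma` compares the lifetime direct medical costs of two first-line
catheter-ablation strategies for paroxysmal atrial fibrillation (PAF) —
cryoballoon ablation (CBA) and radiofrequency ablation (RFA) — from the
Japanese public payer's perspective. Because the package's own
meta-analysis machinery (and the wider literature) finds no significant
difference in AF recurrence between the two energy sources, the economic
comparison is a *cost-minimization analysis* (CMA): both strategies share
every clinical transition probability, and only costs that attach to the
choice of procedure can differ. There are no utilities or QALYs anywhere
in the model; a CMA has none by construction.

The package has two halves that meet in the analysis drivers:

1. a meta-analysis engine for AF-recurrence effect sizes (risk ratios from
   arm-level counts, hazard ratios from reported CIs, fixed and
   DerSimonian–Laird random-effects pooling, Cochran's Q and I²,
   contact-force subgroup splits), and
2. an economic model: a two-year decision tree feeding a lifetime
   annual-cycle Markov cohort model, a cost-breakdown report, and one-way
   deterministic sensitivity analysis (DSA).

# The meta-analysis engine

Per-study effects are computed on the log scale. For a study reporting
arm-level counts, the log risk ratio is
$\log\mathrm{RR} = \log\frac{a/n_t}{c/n_c}$ with
$\mathrm{SE} = \sqrt{1/a - 1/n_t + 1/c - 1/n_c}$, with a continuity
correction of 0.5 added to all four cells only when an event cell is zero
(the standard practice; the correction size is an argument). For a study
reporting a hazard ratio with a 95% CI, the SE is back-calculated as
$(\log u - \log \ell)/(2 \times 1.959964)$. RR and HR studies are pooled
separately; no HR is ever imputed from counts.

Fixed-effect pooling is inverse-variance weighting. The random-effects
model uses the DerSimonian–Laird moment estimator
$\hat\tau^2 = \max\!\left(0, \frac{Q - (k-1)}{S_1 - S_2/S_1}\right)$,
chosen because it remains the conventional default in this clinical
literature; Q, I² and the Q p-value are reported from fixed-effect
weights. I² is truncated at zero (`max(0, (Q - df)/Q)`, defined as 0 when
Q = 0). Randomized trials and propensity-matched cohorts are pooled
without design weighting. In the contact-force subgroup split, studies
whose RFA type cannot be determined are excluded from both subgroups but
kept in the overall pool. Studies with under six months of follow-up are
excluded from pooling altogether.

The implementation is authored in the package and cross-checked in the
test suite against `metafor` (fixed and DL models, agreement to 1e-10)
and against a deliberately naive loop-arithmetic oracle (agreement to
1e-12 on small rational inputs).

# The decision tree (years 1–2)

Patients enter having chosen a first procedure. Recurrence after the
first ablation occurs with probability 0.268; of those, 78% undergo a
second ablation at 6 months. Recurrence after a re-ablation is the
first-ablation probability scaled by a relative risk of 1.61 (capped at
1, so DSA extremes cannot create invalid cohorts); of those recurring
again, 37% undergo a third ablation at 18 months, the maximum. Repeat
procedures are RFA or CBA with constant claims-data proportions that
depend on the preceding procedure, which is why intervention costs differ
between strategies beyond the first procedure.

Three conventions matter and were fixed once:

* **Discounting**: the procedures at entry and 6 months are undiscounted;
  the 18-month procedure (and its attached event costs) is discounted one
  full year at the 2%/year rate. Annual-step alternatives do not
  reproduce a coherent tree-side cost surface; this convention does, to
  within rounding of the reference values the model is built around.
  A consequence worth noting: the discount rate touches the strategy
  difference only through the 18-month term, whose contribution to the
  difference is a few yen, so varying the rate over 0–4% moves the total
  difference by well under one yen.
* **No attrition between stages**: expected procedure counts use branch
  probabilities only; the per-procedure death risk (1.2%) and ischemic
  stroke risk (0.7%) do not suppress later procedures. Whether patients
  dying before 6/18 months should block later procedures is a legitimate
  modelling question; the expected-value accounting here deliberately
  does not do it, and the microsimulation oracle in the tests follows the
  same convention.
* **Cost buckets**: only the six named complications (esophageal injury,
  tamponade, PV stenosis, phrenic nerve palsy, vascular, groin) enter the
  "serious adverse event" bucket. Tree stroke events are split fatal /
  non-fatal at the 28-day case fatality (7.3%) and costed into the two
  stroke buckets, not into the SAE bucket.

**Markov entry.** Patients who received a third ablation enter the Markov
model in year 3; everyone else enters in year 2. Within each subcohort the
per-procedure stroke and death fractions (3 procedures for the year-3
subcohort; the subcohort's expected procedure count for the year-2 one)
are overlaid proportionally on the AF+/AF− split: stroke survivors enter
the IS state regardless of AF symptoms (stroke dominates), deaths and
fatal strokes enter Dead, and the remaining cohort splits into AF+
(recurrence left untreated or unresolved after the final ablation) and
AF−. The entry distribution is identical across strategies because every
probability in it is shared — this is what makes the Markov side cancel.

# The Markov model (lifetime)

States: AF−, AF+, IS (incident stroke year), Post-IS, Dead. One-year
cycles continue the tree's year numbering, discounted at
$(1+r)^{-(t-1)}$; the cohort ages one year per cycle from 64.6 with a
fixed 67/33 male/female mix (no differential survival by sex).

Within a cycle, background death (sex-blended life-table probability at
the floored age) is applied first; stroke (0.24%/year) and — from AF−
only — recurrence (7.7%/year in the first two Markov years, 4.1%
after, counted as years since *that subcohort's* Markov entry) then
partition the survivors additively. Rows are exactly stochastic without
renormalization; the stroke and recurrence probabilities sum far below 1
over all DSA ranges, and the engine raises an error naming the cycle if a
parameter set ever violates that.

The IS state resolves in one cycle: death is the 28-day case fatality
plus the 1-year mortality among 28-day survivors
(0.073 + 0.927 × 0.127 ≈ 0.191); survivors move to Post-IS, where no
repeat stroke occurs and annual mortality is 8.5%, floored at the
background rate so the state is never safer than the general population
at high ages. Incident Markov strokes accrue the fatal / non-fatal event
costs at the 28-day split; entrants who had their stroke in the tree were
already costed there and accrue no second event cost — they do, however,
pass through the IS state's composite mortality like any other occupant,
which double-counts their 28-day risk slightly. This is deliberate: the
transition contract is per-state, not per-origin, the effect is tiny, and
it cancels exactly between strategies.

State costs (per person-year occupied, accrued on start-of-cycle
occupancy): AF− ¥36,373, AF+ ¥172,780, Post-IS ¥67,486. No half-cycle
correction is applied — none is needed for the tree-side quantities the
model is anchored to, and the Markov buckets cancel between strategies
regardless. The horizon runs to age 110, where the life table closes at
probability 1.

**The life table is synthetic.** No specific national table is named for
the background mortality, so the bundled table is a Gompertz–Makeham
fixture, $q_x = \min(1,\, a + b e^{c\,\mathrm{age}})$ with
$a = 5\times10^{-4}$, $b = 10^{-5}$, $c = 0.1$ and a 1.6× male excess —
parameters chosen once so a 64.6-year-old mixed cohort has a remaining
life expectancy of roughly two decades, the realistic scale for a
contemporary high-income population. Consequently the *absolute* Markov
bucket magnitudes (and the absolute lifetime totals) are
fixture-dependent and are validated by properties — strategy equality of
every Markov bucket, closed-form annuity agreement to 1e-9, cohort
conservation — rather than by external reference values. The tree-side
costs and every difference row are life-table independent.

# The cost-minimization report

`run_cma()` evaluates both strategies under one shared parameter set and
reports seven component rows plus totals, with the difference column on
the RFA − CBA convention (negative = RFA cheaper). The total difference
is computed as the sum of the component differences, so the identity
*difference.total = difference.intervention + difference.sae* holds
bit-exactly (all Markov rows subtract to exact zero). JPY values are
computed in floating point and rendered rounded to the yen; USD at a
fixed 150 JPY/USD, rounded to the dollar.

# One-way sensitivity analysis

Every parameter with a published range is set to its lower and upper
bound in turn (95% CI bounds where the source reported them, ±20%
otherwise, 0–4% for the discount rate), the CMA re-run, and the total
difference recorded; entries are sorted by span, ties alphabetical.
Complication probabilities printed as a single shared RFA/CBA row vary
jointly for both procedures; procedure-specific rows vary independently.
The third-ablation RFA proportion after a second CBA has no published
range and is not varied. A bound that would violate a type invariant is
clipped into [0, 1] with a warning. Markov-only parameters (starting age,
sex mix, Markov recurrence/stroke/mortality, state costs) have exactly
zero span by the cancellation argument; the two procedure unit costs
dominate the tornado by an order of magnitude.

# Synthetic study sets

`simulate_meta_dataset()` stands in for the unavailable trial-level data.
Per study: a baseline (RFA-arm) recurrence risk is drawn uniformly from
0.20–0.45, per-arm sizes uniformly from 25–375 (the range of the real
evidence base), a study-level log RR from
$\mathcal{N}(\log 0.93, \tau^2 = 0.01)$, and binomial events per arm with
the CBA-arm risk equal to baseline × RR. Study type is RCT with
probability 12/18 and the comparator is contact-force RFA with
probability 8/14 (the share among studies with a determinable type).
Generation is reproducible under a seed and restores the global RNG
state.

What this emulates: sampling error, between-study heterogeneity on the
log-ratio scale, and the size distribution of a realistic evidence base.
What it does not: censoring and time-to-event structure (HR studies are
exercised through the closed-form CI back-calculation instead),
correlation between arm size and effect, publication bias, or
risk-of-bias heterogeneity. Passing recovery tests therefore demonstrate
the *estimator's* correctness on well-specified binomial data, not
robustness to those real-data pathologies.

# Numerical choices and problem sizes

* Probabilities × relative risks are capped at 1; costs are stored as
  exact integers of JPY and all expectation arithmetic is double
  precision.
* The 95% normal quantile is fixed at 1.959964 in both CI construction
  and SE back-calculation, so the two operations are exact inverses.
* Ties in the tornado are broken alphabetically to make output
  deterministic; identical inputs give byte-identical CSVs.
* Test and validation problem sizes, chosen as the package's own
  trade-off between Monte-Carlo resolution and a test suite that runs in
  about a minute: parameter recovery uses 500 replicates at k = 40
  studies of 300–500 per arm (bias tolerance 0.02, coverage band
  95% ± 3%); null-set fixed-model coverage uses 1000 replicates at
  k = 18; the tree microsimulation oracle uses 10⁶ patients (agreement
  within 3 Monte-Carlo SEs); between-study-variance recovery uses 200
  replicates.

# Known limitations

* The life table is a parametric fixture; absolute lifetime totals move
  with it (differences do not).
* The decision tree is expected-value only; the microsimulation exists as
  a test oracle, not as a user-facing engine.
* No probabilistic sensitivity analysis, no network meta-analysis, no
  publication-bias diagnostics — all outside the analysis this package
  implements.
* Repeat strokes, anticoagulation-dependent stroke risk and
  quality-of-life outcomes are not modelled.
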