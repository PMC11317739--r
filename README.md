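# afablcma

Meta-analysis and lifetime cost-minimization modelling of **cryoballoon
ablation (CBA) versus radiofrequency ablation (RFA)** for paroxysmal
atrial fibrillation (PAF), from the Japanese public payer's perspective.

The package is written for health-economics and biostatistics
practitioners who need the full analytic chain behind this comparison as
tested, reusable code:

* **Meta-analysis engine** — per-study log risk ratios from arm-level
  counts (`rr_effect()`), log hazard ratios back-calculated from reported
  95% CIs (`hr_effect()`), inverse-variance fixed-effect pooling
  (`pool_fixed()`) and DerSimonian–Laird random-effects pooling
  (`pool_random_dl()`), Cochran's Q / I² heterogeneity
  (`heterogeneity()`), and contact-force subgroup splits
  (`subgroup_pool()`).
* **Decision tree** (`run_tree()`) — two years: first ablation at entry,
  optional repeat ablations at 6 and 18 months (repeat procedures are RFA
  or CBA with constant claims-data proportions), per-procedure
  complications, ischemic stroke and death.
* **Markov cohort model** (`run_markov()`) — lifetime annual cycles over
  AF symptom (−/+), incident stroke, post-stroke and death states, with
  sex-blended life-table background mortality, state costs and 2%/year
  discounting.
* **Cost-minimization report** (`run_cma()`) — the per-strategy totals,
  seven component cost rows and the RFA − CBA difference column, with USD
  conversion (`to_usd()`).
* **One-way sensitivity analysis** (`one_way_dsa()`) — tornado-ordered
  results over the published parameter ranges.
* **Synthetic-data generators** (`simulate_meta_dataset()`,
  `make_life_table()`) — study sets with known truth and parametric
  Gompertz–Makeham life tables, since neither the trial-level counts nor
  a specific national life table are deposited.

The core economic logic: both strategies share every clinical transition
probability (the meta-analysis finds no significant recurrence
difference, so equality is assumed), hence all Markov-side cost rows
cancel exactly between strategies and the cost difference is driven
entirely by the decision tree — the procedure unit costs
(¥2,256,516 RFA vs ¥2,609,223 CBA), the repeat-procedure mixes, and the
per-procedure complication profiles.

## Worked example

```r
library(afablcma)

p  <- load_params(system.file("extdata", "params_default.yaml",
                              package = "afablcma"))
lt <- make_life_table()   # synthetic Gompertz–Makeham fixture
print(run_cma(p, lt))
```

```
Cost-minimization analysis (JPY, discounted; difference = RFA - CBA)
    component       rfa       cba difference
        total 4,459,796 4,813,084   -353,289
 intervention 2,803,539 3,157,643   -354,103
          sae    47,082    46,268        814
       af_neg   315,995   315,995          0
       af_pos 1,218,701 1,218,701          0
     is_fatal     7,977     7,977          0
  is_nonfatal    47,009    47,009          0
      post_is    19,492    19,492          0
RFA saves 353,289 JPY (USD 2,355) over CBA
```

Reading the table: performing RFA first is ¥354,103 cheaper in
intervention costs but ¥814 more expensive in complication costs, for a
net saving of ¥353,289 (USD 2,355 at 150 JPY/USD). The five Markov rows
are identical across strategies — their difference is exactly zero — so
the absolute lifetime totals move with the (synthetic) life table while
the difference column does not.

The numbered scripts under `analysis/` run the full workflow and write
their tables under `results/`:

```sh
Rscript analysis/01_pool_recurrence.R     # pooled recurrence on a synthetic evidence base
Rscript analysis/02_base_case_cma.R       # the base-case cost breakdown above
Rscript analysis/03_sensitivity_tornado.R # one-way DSA / tornado table
```

## Layout

```
R/                   params, meta, tree, markov, cma, dsa, synth modules
inst/extdata/        bundled base-case configuration (YAML)
analysis/            numbered workflow drivers (write to results/)
scripts/acceptance.R headline-quantity reproduction
tests/testthat/      unit, property and end-to-end suites
vignettes/           methods vignette (model, conventions, limitations)
```
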