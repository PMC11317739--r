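#!/usr/bin/env Rscript

# Meta-analysis of AF recurrence, CBA vs RFA, on a synthetic evidence base.
#
# The trial-level event counts behind the published forest plots are not
# deposited, so this driver generates a study set emulating that evidence
# base (18 studies: 12 RCTs and 6 propensity-matched cohorts, true risk
# ratio 0.93 with modest heterogeneity) and runs the full pooling chain:
# per-study log risk ratios, fixed and DerSimonian-Laird random-effects
# pools, Cochran's Q / I2, and the contact-force subgroup split.

library(afablcma)

dir.create("results", showWarnings = FALSE)

spec <- meta_sim_spec(k = 18, true_log_rr = log(0.93), tau2 = 0.01, seed = 20240601)
studies <- simulate_meta_dataset(spec)
write_studies(studies, "results/studies_synthetic.csv")

est <- effects_from_studies(studies, "RR")
fixed <- pool_fixed(est)
random <- pool_random_dl(est)

cat("Pooled AF recurrence, CBA vs RFA (synthetic evidence base, k = 18):\n")
print(fixed)
print(random)

forest <- forest_table(est)
write.csv(forest, "results/forest_table.csv", row.names = FALSE)

pooled_rows <- do.call(rbind, lapply(list(fixed, random), function(x) {
  data.frame(measure = x$measure, method = x$method, k = x$k,
             ratio = exp(x$log_pooled), ci_low = x$ci95[1],
             ci_high = x$ci95[2], q = x$q, df = x$df, p_q = x$p_q,
             i2 = x$i2, tau2 = x$tau2)
}))

cat("\nContact-force subgroup split:\n")
sg <- subgroup_pool(est)
for (g in names(sg)) {
  if (is.null(sg[[g]])) next
  cat(sprintf("  %s (k = %d):\n", g, sg[[g]]$fixed$k))
  print(sg[[g]]$fixed)
  pooled_rows <- rbind(pooled_rows, data.frame(
    measure = "RR", method = paste0("fixed_", g), k = sg[[g]]$fixed$k,
    ratio = exp(sg[[g]]$fixed$log_pooled),
    ci_low = sg[[g]]$fixed$ci95[1], ci_high = sg[[g]]$fixed$ci95[2],
    q = sg[[g]]$fixed$q, df = sg[[g]]$fixed$df, p_q = sg[[g]]$fixed$p_q,
    i2 = sg[[g]]$fixed$i2, tau2 = sg[[g]]$fixed$tau2))
}
write.csv(pooled_rows, "results/meta_pooled.csv", row.names = FALSE)

cat("\nAs in the published analysis, the pooled ratio sits close to 1 with a",
    "\nCI spanning it: no significant recurrence difference, which is what",
    "\nmotivates a cost-minimization (rather than cost-utility) comparison.\n")
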