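#!/usr/bin/env Rscript

# Base-case cost-minimization analysis: two-year decision tree plus
# lifetime Markov model for both first-line strategies under the bundled
# base-case inputs and the synthetic life table.

library(afablcma)

dir.create("results", showWarnings = FALSE)

p <- load_params(system.file("extdata", "params_default.yaml",
                             package = "afablcma"))
lt <- make_life_table()
write_life_table(lt, "results/life_table_synthetic.csv")

rep <- run_cma(p, lt)
print(rep)

tab <- cma_table(rep, usd = TRUE)
write.csv(tab, "results/cost_breakdown.csv", row.names = FALSE)

for (s in c("rfa", "cba")) {
  tr <- rep$markov[[s]]$trace
  write.csv(tr, sprintf("results/markov_trace_%s.csv", s), row.names = FALSE)
}

d <- rep$breakdown
cat(sprintf(
  "\nThe tree-side rows drive the whole difference: intervention %+.0f JPY\nand complications %+.0f JPY (RFA - CBA); every Markov row cancels exactly\nbecause both strategies share all transition probabilities. The lifetime\ntotals depend on the synthetic life table, but the difference does not.\n",
  d$difference[d$component == "intervention"],
  d$difference[d$component == "sae"]))
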