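#!/usr/bin/env Rscript
# Step 4 — cost-effectiveness ladders.
#
# Ranks each group's strategies by cost, removes dominated and
# extended-dominated rows, and reports ICERs between consecutive
# undominated strategies plus the cost-effective pick at the
# $100,000/QALYG willingness-to-pay threshold. Requires step 3's output.

library(crcscreen)

outcomes <- read_table_file("results/strategy_outcomes.tsv")
rows <- list()
for (g in unique(outcomes$group)) {
  sub <- outcomes[outcomes$group == g, c("strategy", "cost", "qalyg")]
  lad <- build_icer_ladder(sub, wtp = 1e5)
  rows[[g]] <- cbind(group = g, as.data.frame(lad))
  und <- lad[lad$status == "undominated", ]
  cat(sprintf("%-12s undominated: %s; cost-effective at $100k/QALYG: %s\n",
              g, paste(und$strategy, collapse = ", "),
              lad$strategy[lad$cost_effective]))
  if (any(lad$dominant)) {
    cat(sprintf("             dominant strategy: %s\n",
                lad$strategy[lad$dominant]))
  }
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write_table(tab, path = "results/cea_ladders.tsv")
cat("CEA ladders written to results/cea_ladders.tsv\n")
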