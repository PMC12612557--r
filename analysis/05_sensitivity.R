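#!/usr/bin/env Rscript
# Step 5 — one-way and probabilistic sensitivity analyses (desk scale).
#
# Tornado: incremental net monetary benefit (CTC-only minus status quo)
# at the wide endpoint of each behavioural/test/cost parameter,
# seed-aligned, 1,500 persons per evaluation. PSA: 200 parameter draws
# from the published uncertainty distributions, 500 persons per
# simulation, CEAC over $10k-$500k. The production-scale analogues (5,000
# draws x 100 calibrated sets x 500,000 persons) are configuration, not
# defaults.

library(crcscreen)

dir.create("results", showWarnings = FALSE)
seed <- 1L
for (g in c("White men", "Black men")) {
  gtag <- gsub(" ", "_", tolower(g))
  truth <- make_truth(seed, g)
  ev <- crc_sa_evaluator(g, truth$params, n = 1500, seed = seed + 2)
  tor <- one_way_sa(crc_sa_config(), default_owsa_ranges(), ev, wtp = 1e5)
  write_table(tor, path = sprintf("results/tornado_%s.tsv", gtag))
  cat(sprintf("%-12s top tornado parameter: %s (swing $%.0f per 1000)\n",
              g, tor$param[1], tor$swing[1]))

  fn <- crc_psa_outcome_fn(g, truth$params, n = 500)
  psa <- run_psa(fn, n_draws = 200, seed = seed + 3)
  write_table(psa$ceac, path = sprintf("results/ceac_%s.tsv", gtag))
  write_table(psa$frontier, path = sprintf("results/frontier_%s.tsv", gtag))
  at100k <- psa$ceac[psa$ceac$wtp == 1e5, ]
  lead <- at100k[which.max(at100k$probability), ]
  cat(sprintf("%-12s most likely cost-effective at $100k: %s (%.0f%% of draws)\n",
              g, lead$strategy, 100 * lead$probability))
}
cat("Sensitivity tables written under results/\n")
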