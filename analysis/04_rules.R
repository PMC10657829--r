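#!/usr/bin/env Rscript
# Stage 4 — Apriori association rules per stage at support 0.16 /
# confidence 0.9 over the high-frequency herbs, plus the hub herbs of the
# parallel-coordinates rule network.

library(herbmicrobeMR)

prescriptions <- read_prescriptions("results/inputs/prescriptions.csv")
dir.create("results/rules", showWarnings = FALSE, recursive = TRUE)

floors <- c(compensated = 10L, decompensated = 20L)
for (st in unique(prescriptions$stage)) {
  sub <- prescriptions[prescriptions$stage == st, ]
  cfg <- rule_config(min_support = 0.16, min_confidence = 0.9,
                     frequency_floor = floors[[st]])
  mined <- mine_rules(sub, cfg)
  write.table(mined$rules, sprintf("results/rules/rules_%s.tsv", st),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d rules", st, nrow(mined$rules)))
  if (nrow(mined$rules) > 0) {
    cat(sprintf("; top support %.2f%% ({%s} => {%s}), max lift %.2f; all lift > 1: %s",
                100 * mined$rules$support[1], mined$rules$antecedent[1],
                mined$rules$consequent[1], max(mined$rules$lift),
                all(mined$rules$lift > 1)))
    net <- rule_network_table(mined$rules)
    write.table(net$table, sprintf("results/rules/rule_network_%s.tsv", st),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("\n%s hub herbs: %s", st,
                paste(head(net$hubs$item, 5), collapse = ", ")))
  }
  cat("\n")
}
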