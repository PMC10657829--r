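#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs.
#
# Emulates the two literature-mined prescription corpora (98 compensated,
# 241 decompensated prescriptions) with stage-specific planted herb blocks,
# the three overlapping target sets with a planted hub, and two-sample GWAS
# summary statistics under a linear causal model. Everything downstream
# reads the files written here.

library(herbmicrobeMR)

seed <- 20260923L
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)

herbs <- sprintf("Herb%02d", 1:40)
spec <- corpus_spec(
  n_per_stage = c(compensated = 98, decompensated = 241),
  herb_universe = herbs,
  core_blocks = list(
    # a "compensated-stage" block (liver-soothing core) and a
    # "decompensated-stage" block (water-draining core)
    list(herbs = herbs[1:3], prob = c(compensated = 0.6, decompensated = 0.2)),
    list(herbs = herbs[4:6], prob = c(compensated = 0.15, decompensated = 0.55))),
  background_rate = 0.22,
  herbs_per_prescription_range = c(2L, 24L),
  seed = child_seed(seed, "corpus"))
prescriptions <- simulate_corpus(spec)
write.csv(prescriptions, "results/inputs/prescriptions.csv", row.names = FALSE)
cat(sprintf("corpus: %d prescriptions, %d herb occurrences, %.2f herbs/prescription\n",
            length(unique(prescriptions$study_id)), nrow(prescriptions),
            nrow(prescriptions) / length(unique(prescriptions$study_id))))

tg <- simulate_target_sets(
  n_universe = 500,
  regions = c(A = 50, B = 40, C = 30, AB = 20, AC = 15, BC = 10, ABC = 85),
  hub_degree = 12, n_background_edges = 60,
  seed = child_seed(seed, "targets"))
set_df <- do.call(rbind, lapply(names(tg$sets), function(lb)
  data.frame(label = lb, gene = tg$sets[[lb]])))
write.table(set_df, "results/inputs/target_sets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tg$edges, "results/inputs/ppi_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("target sets: %s genes; planted hub %s (degree %d)\n",
            paste(lengths(tg$sets), collapse = "/"), tg$hub, 12))

gw <- simulate_gwas(gwas_sim_spec(
  n_snps = 30, theta = log(1.27),   # a protective/risk effect of OR 1.27
  invalid_fraction = 0, seed = child_seed(seed, "gwas")))
write.table(gw$exposure, "results/inputs/exposure_gwas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gw$outcome, "results/inputs/outcome_gwas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
ld_df <- data.frame(rsid_a = rep(rownames(gw$ld), ncol(gw$ld)),
                    rsid_b = rep(colnames(gw$ld), each = nrow(gw$ld)),
                    r2 = as.vector(gw$ld))
ld_df <- ld_df[ld_df$rsid_a < ld_df$rsid_b & ld_df$r2 > 0, ]
write.table(ld_df, "results/inputs/ld_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("gwas: %d SNPs simulated at theta = log(1.27) = %.4f\n",
            nrow(gw$exposure), log(1.27)))
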