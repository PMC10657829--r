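#!/usr/bin/env Rscript
# Stage 3 — do the two cirrhosis stages use distinguishable herb profiles?
#
# Bray-Curtis dissimilarity over binary herb profiles, PCoA with per-axis
# variance explained, one-way PERMANOVA on stage labels, and a two-class
# PLS-DA as a supervised check.

library(herbmicrobeMR)

prescriptions <- read_prescriptions("results/inputs/prescriptions.csv")
dir.create("results/ordination", showWarnings = FALSE, recursive = TRUE)

inc <- incidence_matrix(prescriptions)
stage <- attr(inc, "stage")
d <- bray_curtis(inc)

ord <- pcoa(d, k = 2)
coords <- data.frame(study_id = rownames(ord$coordinates), stage = stage,
                     ord$coordinates)
write.table(coords, "results/ordination/pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCoA: axis 1 explains %.2f%%, axis 2 %.2f%% (negative eigenvalues: %d)\n",
            ord$variance_explained[1], ord$variance_explained[2],
            sum(ord$eigenvalues < 0)))

perm <- permanova(d, stage, n_permutations = 999, seed = 71)
cat(sprintf("PERMANOVA: pseudo-F = %.3f, p = %.3g (%d permutations)\n",
            perm$pseudo_F, perm$p_value, perm$n_permutations))

pls <- plsda(inc, stage, n_components = 3)
cat(sprintf("PLS-DA captured X-variance: %s\n",
            paste(sprintf("%.1f%%", pls$percent_variation), collapse = ", ")))

write.table(
  data.frame(statistic = c("pseudo_F", "p_value",
                           "PCo1_pct", "PCo2_pct",
                           paste0("plsda_comp", 1:3, "_pct")),
             value = c(perm$pseudo_F, perm$p_value, ord$variance_explained[1:2],
                       pls$percent_variation)),
  "results/ordination/summary.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
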