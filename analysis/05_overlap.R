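#!/usr/bin/env Rscript
# Stage 5 — therapeutic-target overlap and network analysis: three-way
# intersection of herb-ingredient, microbe-metabolite and disease target
# sets; degree-based hub ranking on the score-thresholded interaction
# network; hypergeometric pathway over-representation of the cross-targets;
# and the microbe -> metabolite -> target -> pathway linkage table.

library(herbmicrobeMR)

dir.create("results/overlap", showWarnings = FALSE, recursive = TRUE)
sets <- read_target_sets("results/inputs/target_sets.tsv")
edges <- read_edge_list("results/inputs/ppi_edges.tsv")

ct <- cross_targets(sets)
write.table(data.frame(region = names(ct$cardinality),
                       cardinality = ct$cardinality),
            "results/overlap/venn_regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("cross-targets (three-way intersection): %d genes\n",
            length(ct$cross_targets)))

hubs <- hub_ranking(edges, nodes = unique(unlist(sets)), score_cutoff = 0.4)
write.table(hubs, "results/overlap/hub_ranking.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("top hub gene: %s (degree %d)\n", hubs$gene[1], hubs$degree[1]))

# synthetic pathway map over the target universe; enrichment of cross-targets
set.seed(23)
universe <- sort(unique(unlist(sets)))
pws <- lapply(1:10, function(i)
  unique(c(sample(ct$cross_targets, 6), sample(universe, 25))))
names(pws) <- sprintf("pathway_%02d", 1:10)
enr <- pathway_enrichment(ct$cross_targets, pws, universe)
write.table(enr[, c("pathway", "pathway_size", "overlap", "p", "q")],
            "results/overlap/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("most enriched pathway: %s (overlap %d, q = %.2g)\n",
            enr$pathway[1], enr$overlap[1], enr$q[1]))

# linkage chains restricted to the top-7 core targets
core <- head(hubs$gene, 7)
mm <- data.frame(microbe = rep(c("Lachnospiraceae", "Veillonella", "Coprococcus"),
                               each = 2),
                 metabolite = c("butyrate", "acetate", "propionate", "lactate",
                                "butyrate", "succinate"))
mt <- data.frame(metabolite = rep(unique(mm$metabolite), each = 2),
                 target = sample(c(core, universe[1:3]), 10, replace = TRUE))
tp <- data.frame(target = core, pathway = sample(names(pws), 7, TRUE))
lt <- linkage_table(core, mm, mt, tp)
write.table(lt, "results/overlap/linkage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("linkage rows (microbe -> metabolite -> core target -> pathway): %d\n",
            nrow(lt)))
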