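test_that("ADME filter keeps boundary values and drops sub-threshold compounds", {
  rec <- data.frame(compound = c("c1", "c2", "c3", "c4"),
                    oral_bioavailability = c(30.0, 29.9, 55, 80),
                    drug_likeness = c(0.18, 0.99, 0.17, 0.5))
  kept <- adme_filter(rec)
  expect_equal(kept$compound, c("c1", "c4"))
  # synthetic table with a known pass count
  set.seed(8)
  tab <- data.frame(oral_bioavailability = runif(200, 0, 60),
                    drug_likeness = runif(200, 0, 0.4))
  k <- sum(tab$oral_bioavailability >= 30 & tab$drug_likeness >= 0.18)
  expect_equal(nrow(adme_filter(tab)), k)
})

test_that("three-way intersections obey exact set algebra", {
  sets <- list(herb = c("a", "b", "c", "d"),
               microbe_metabolite = c("c", "d", "e"),
               disease = c("d", "e", "f"))
  ct <- cross_targets(sets)
  expect_equal(ct$cross_targets, "D")
  expect_equal(unname(ct$cardinality),
               c(2, 0, 1, 1, 0, 1, 1))  # A,B,C,AB,AC,BC,ABC exclusive regions
  # inclusion-exclusion: regions partition the union
  expect_equal(sum(ct$cardinality), length(unique(toupper(unlist(sets)))))
  # identical sets put everything in the triple region
  same <- list(x = c("g1", "g2"), y = c("g1", "g2"), z = c("g2", "g1"))
  cs <- cross_targets(same)
  expect_equal(unname(cs$cardinality["ABC"]), 2)
  expect_equal(sum(cs$cardinality), 2)
  # random sets: partition identity across seeds
  for (seed in 1:20) {
    set.seed(seed)
    rs <- lapply(1:3, function(i) sample(sprintf("g%02d", 1:30), sample(5:20, 1)))
    names(rs) <- c("s1", "s2", "s3")
    cr <- cross_targets(rs)
    expect_equal(sum(cr$cardinality), length(unique(toupper(unlist(rs)))))
  }
})

test_that("hub ranking applies the score cutoff with lexicographic ties", {
  star <- data.frame(gene_a = "HUB", gene_b = sprintf("N%d", 1:7),
                     combined_score = 0.9)
  r <- hub_ranking(star)
  expect_equal(r$gene[1], "HUB")
  expect_equal(r$degree[1], 7L)
  weak <- star; weak$combined_score <- 0.39
  expect_true(all(hub_ranking(weak)$degree == 0))
  tie <- data.frame(gene_a = c("B", "A"), gene_b = c("C", "C"),
                    combined_score = 0.8)
  rt <- hub_ranking(tie)
  expect_equal(rt$gene, c("C", "A", "B"))
  expect_error(hub_ranking(data.frame(gene_a = "X", gene_b = "X",
                                      combined_score = 0.5)), "self-loop")
})

test_that("hypergeometric enrichment equals exhaustive enumeration on 20 genes", {
  universe <- sprintf("u%02d", 1:20)
  pathway <- universe[1:5]
  draws <- utils::combn(20, 5)          # all C(20,5) possible gene sets
  for (target_overlap in c(5, 3, 1, 0)) {
    # enumeration oracle: fraction of draws with overlap >= observed
    overlaps <- apply(draws, 2, function(ix) sum(ix <= 5))
    gene_set <- c(universe[seq_len(target_overlap)],
                  universe[5 + seq_len(5 - target_overlap)])
    res <- pathway_enrichment(gene_set, list(pw = pathway), universe)
    expect_equal(res$p, mean(overlaps >= target_overlap), tolerance = 1e-12)
  }
  # saturated universe: p forced to 1
  sat <- pathway_enrichment(pathway, list(pw = pathway), pathway)
  expect_equal(sat$p, 1)
})

test_that("BH adjustment and empty-pathway handling behave", {
  universe <- sprintf("u%03d", 1:100)
  pws <- list(p1 = universe[1:10], p2 = universe[11:40],
              p3 = c("zzz1", "zzz2"))
  expect_warning(res <- pathway_enrichment(universe[1:10], pws, universe),
                 "zzz|skipped|no universe")
  expect_equal(nrow(res), 2)
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
  expect_error(pathway_enrichment(c(universe[1], "NOTINUNIVERSE"), pws, universe),
               "outside")
})

test_that("enrichment p-values are calibrated (super-uniform) under random sets", {
  set.seed(6)
  universe <- sprintf("g%04d", 1:800)
  pws <- lapply(1:6, function(i) sample(universe, sample(80:300, 1)))
  names(pws) <- paste0("pw", 1:6)
  ps <- replicate(2000, {
    e <- pathway_enrichment(sample(universe, 40), pws, universe)
    e$p[sample(nrow(e), 1)]
  })
  for (a in c(0.05, 0.1, 0.25, 0.5)) {
    mc <- sqrt(a * (1 - a) / 2000)
    expect_lte(mean(ps <= a), a + 3 * mc)    # valid (conservative) p-values
  }
  expect_gt(mean(ps <= 0.5), 0.25)           # but not degenerate
})

test_that("linkage table joins microbe-metabolite-target-pathway chains", {
  mm <- data.frame(microbe = c("Lachnospiraceae", "Lachnospiraceae", "Veillonella"),
                   metabolite = c("butyrate", "acetate", "lactate"))
  mt <- data.frame(metabolite = c("butyrate", "acetate", "lactate", "butyrate"),
                   target = c("MAPK1", "STAT3", "AKT1", "VEGFA"))
  tp <- data.frame(target = c("MAPK1", "STAT3", "VEGFA"),
                   pathway = c("MAPK signaling", "JAK-STAT", "VEGF signaling"))
  core <- c("MAPK1", "STAT3", "VEGFA")   # AKT1 outside the core set
  lt <- linkage_table(core, mm, mt, tp)
  expect_equal(nrow(lt), 3)
  expect_false("AKT1" %in% lt$target)
  expect_true(all(lt$target %in% core))
  # single chain gives a single row
  single <- linkage_table("MAPK1", mm[1, ], mt[1, ], tp[1, ])
  expect_equal(nrow(single), 1)
  expect_equal(single$pathway, "MAPK signaling")
})

test_that("target-set, edge-list and GMT readers round-trip plain-text files", {
  ts <- tempfile(fileext = ".tsv")
  writeLines(c("label\tgene", "herb\ttp53", "herb\tMYC ", "disease\tTP53"), ts)
  sets <- read_target_sets(ts)
  expect_equal(sets$herb, c("TP53", "MYC"))
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("pwA\tdesc\tTP53\tMYC", "pwB\tdesc\tEGFR"), gmt)
  pm <- read_gmt(gmt)
  expect_equal(pm$pwA, c("TP53", "MYC"))
  el <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tcombined_score", "TP53\tMYC\t0.8"), el)
  expect_equal(read_edge_list(el)$combined_score, 0.8)
})
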