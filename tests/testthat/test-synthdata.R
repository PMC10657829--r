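test_that("corpus generator honors degenerate block probabilities", {
  spec <- corpus_spec(
    n_per_stage = c(compensated = 20),
    herb_universe = c("A", "B", "C", "D", "E"),
    core_blocks = list(list(herbs = c("A", "B", "C"),
                            prob = c(compensated = 1))),
    background_rate = 0,
    herbs_per_prescription_range = c(3L, 5L),
    seed = 11)
  corp <- simulate_corpus(spec)
  per_presc <- split(corp$herb, corp$study_id)
  expect_length(per_presc, 20)
  for (h in per_presc) expect_setequal(h, c("A", "B", "C"))
})

test_that("identical seeds give byte-identical corpora; streams are name-keyed", {
  spec <- corpus_spec(c(compensated = 15, decompensated = 10),
                      sprintf("H%02d", 1:12), background_rate = 0.3,
                      herbs_per_prescription_range = c(2L, 8L), seed = 7)
  expect_identical(simulate_corpus(spec), simulate_corpus(spec))
  spec2 <- spec; spec2$seed <- 8L
  expect_false(identical(simulate_corpus(spec), simulate_corpus(spec2)))
  expect_false(child_seed(7, "corpus") == child_seed(7, "gwas"))
})

test_that("planted block support is recovered within 3 Monte-Carlo SEs", {
  spec <- corpus_spec(c(compensated = 5000), sprintf("H%02d", 1:10),
                      core_blocks = list(list(herbs = c("H01", "H02"),
                                              prob = c(compensated = 0.8))),
                      background_rate = 0.1,
                      herbs_per_prescription_range = c(2L, 10L), seed = 42)
  corp <- simulate_corpus(spec)
  both <- vapply(split(corp$herb, corp$study_id),
                 function(h) all(c("H01", "H02") %in% h), logical(1))
  mc_se <- sqrt(0.8 * 0.2 / 5000)
  expect_lt(abs(mean(both) - 0.8), 3 * mc_se)
})

test_that("corpus spec validation rejects infeasible ranges and empty universes", {
  expect_error(corpus_spec(c(a = 5), character(0)))
  expect_error(corpus_spec(c(a = 5), c("A", "B"),
                           herbs_per_prescription_range = c(1L, 5L)))
  expect_error(corpus_spec(c(a = 5), c("A", "B", "C"),
                           core_blocks = list(list(herbs = c("A", "B", "C"),
                                                   prob = c(a = 1))),
                           herbs_per_prescription_range = c(1L, 2L)))
})

test_that("noise-free GWAS simulation is exactly linear in the causal effect", {
  gw <- simulate_gwas(gwas_sim_spec(n_snps = 25, theta = 0.5,
                                    invalid_fraction = 0, pleiotropy_sd = 0,
                                    measurement_noise = FALSE,
                                    flip_fraction = 0.3,
                                    palindromic_fraction = 0, seed = 3))
  h <- harmonize(gw$exposure, gw$outcome)
  h <- h[h$action_taken != "dropped", ]
  expect_equal(nrow(h), 25)
  expect_equal(h$beta_out, 0.5 * h$beta_exp, tolerance = 1e-12)
})

test_that("summary-statistic standard errors follow the se-maf-n relation", {
  gw <- simulate_gwas(gwas_sim_spec(n_snps = 40, seed = 9))
  ex <- gw$exposure
  # the exposure table reports the minor allele as effect allele
  expect_equal(ex$se, 1 / sqrt(2 * ex$eaf * (1 - ex$eaf) * ex$n),
               tolerance = 1e-12)
  # binary outcome: effective n = cases * controls / total
  ou <- gw$outcome
  n_eff <- 3970 * (377277 - 3970) / 377277
  maf <- pmin(ou$eaf, 1 - ou$eaf)
  expect_equal(ou$se, 1 / sqrt(2 * maf * (1 - maf) * n_eff), tolerance = 1e-12)
})

test_that("LD blocks produce the requested within-block r2 structure", {
  gw <- simulate_gwas(gwas_sim_spec(n_snps = 8, ld_blocks = list(c(3, 0.9)),
                                    seed = 4))
  ld <- gw$ld
  expect_equal(unname(ld[1, 2]), 0.9)
  expect_equal(unname(ld[2, 3]), 0.9)
  expect_equal(unname(diag(ld)), rep(1, 8))
  expect_equal(unname(ld[1, 4]), 0)
  expect_true(all(ld[4:8, 1:3] == 0))
})

test_that("invalid instruments carry the planted pleiotropy, valid ones none", {
  gw <- simulate_gwas(gwas_sim_spec(n_snps = 5000, theta = 0.2,
                                    invalid_fraction = 0.2,
                                    pleiotropy_mean = 0.05,
                                    pleiotropy_sd = 0.01, seed = 12))
  tr <- gw$truth
  expect_equal(sum(tr$invalid), 1000)
  expect_true(all(tr$alpha[!tr$invalid] == 0))
  mc_se <- 0.01 / sqrt(1000)
  expect_lt(abs(mean(tr$alpha[tr$invalid]) - 0.05), 3 * mc_se)
})

test_that("downstream IVW holds its nominal size under the null", {
  reps <- 400
  rej <- vapply(seq_len(reps), function(i) {
    gw <- simulate_gwas(gwas_sim_spec(n_snps = 15, theta = 0,
                                      palindromic_fraction = 0, seed = 20000 + i))
    h <- harmonize(gw$exposure, gw$outcome)
    mr_ivw(h)$p < 0.05
  }, logical(1))
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 3 * mc_se)
})

test_that("target-set generator plants exact region cardinalities and a top hub", {
  tg <- simulate_target_sets(
    n_universe = 400,
    regions = c(A = 50, B = 40, C = 30, AB = 20, AC = 15, BC = 10, ABC = 85),
    hub_degree = 10, seed = 5)
  ct <- cross_targets(tg$sets)
  expect_equal(unname(ct$cardinality["ABC"]), 85)
  expect_equal(unname(ct$cardinality[c("A", "B", "C")]), c(50, 40, 30))
  expect_equal(unname(ct$cardinality[c("AB", "AC", "BC")]), c(20, 15, 10))
  rank <- hub_ranking(tg$edges, nodes = unique(unlist(tg$sets)))
  expect_equal(rank$gene[1], tg$hub)
  expect_gt(rank$degree[1], rank$degree[2])

  disjoint <- simulate_target_sets(n_universe = 100,
                                   regions = c(A = 10, B = 10, C = 10), seed = 6)
  cd <- cross_targets(disjoint$sets)
  expect_true(all(cd$cardinality[c("AB", "AC", "BC", "ABC")] == 0))

  expect_error(simulate_target_sets(n_universe = 10,
                                    regions = c(A = 20, B = 0, C = 0)),
               "infeasible")
})
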