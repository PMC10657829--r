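gwas_row <- function(rsid, p, chrom = 1, pos = 1e6, beta = 0.1, se = 0.01,
                     ea = "A", oa = "C", eaf = 0.3, n = 18340) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = se, p = p, n = n,
             stringsAsFactors = FALSE)
}

test_that("instrument screens apply p-value, clumping and F-statistic in order", {
  # weak instrument: F = (0.1 / 0.05)^2 = 4 < 10
  weak <- gwas_row("rs1", p = 1e-8, beta = 0.1, se = 0.05)
  expect_equal(nrow(select_instruments(weak)), 0)
  expect_equal(attr(select_instruments(weak), "reason"), "no valid instruments")

  # two SNPs 10 kb apart with r2 = 0.5: only the smaller p survives
  ex <- rbind(gwas_row("rs1", 1e-8, pos = 1e6),
              gwas_row("rs2", 1e-6, pos = 1e6 + 1e4))
  ld <- data.frame(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.5)
  got <- select_instruments(ex, ld)
  expect_equal(got$rsid, "rs1")

  # 600 kb apart: outside the clump window, both kept despite r2 = 0.9
  far <- rbind(gwas_row("rs1", 1e-8, pos = 1e6),
               gwas_row("rs2", 1e-6, pos = 1e6 + 6e5))
  ld2 <- data.frame(rsid_a = "rs1", rsid_b = "rs2", r2 = 0.9)
  expect_equal(sort(select_instruments(far, ld2)$rsid), c("rs1", "rs2"))

  # pairs absent from the LD table are treated as independent
  expect_equal(sort(select_instruments(ex, NULL)$rsid), c("rs1", "rs2"))

  # sub-threshold p is excluded before anything else
  ex2 <- rbind(gwas_row("rs1", 1e-4), gwas_row("rs2", 1e-6))
  expect_equal(select_instruments(ex2)$rsid, "rs2")
})

test_that("greedy clumping retains index SNPs by ascending p", {
  ex <- rbind(gwas_row("rs1", 1e-6, pos = 1.00e6),
              gwas_row("rs2", 1e-9, pos = 1.02e6),
              gwas_row("rs3", 1e-7, pos = 1.04e6))
  ld <- data.frame(rsid_a = c("rs1", "rs2"), rsid_b = c("rs2", "rs3"),
                   r2 = c(0.8, 0.8))
  # rs2 (best p) is kept first and clumps away both neighbours it tags
  got <- select_instruments(ex, ld)
  expect_equal(got$rsid, "rs2")
  # a matrix LD input behaves identically
  ldm <- matrix(0, 3, 3, dimnames = list(ex$rsid, ex$rsid))
  ldm["rs1", "rs2"] <- ldm["rs2", "rs1"] <- 0.8
  ldm["rs2", "rs3"] <- ldm["rs3", "rs2"] <- 0.8
  diag(ldm) <- 1
  expect_equal(select_instruments(ex, ldm)$rsid, "rs2")
})

test_that("harmonization aligns, flips and drops by allele configuration", {
  ex <- rbind(gwas_row("rs_same", 1e-8, ea = "A", oa = "C", eaf = 0.2, beta = 0.10),
              gwas_row("rs_swap", 1e-8, ea = "A", oa = "C", eaf = 0.2, beta = 0.10),
              gwas_row("rs_bad",  1e-8, ea = "A", oa = "C", eaf = 0.2, beta = 0.10),
              gwas_row("rs_pal50", 1e-8, ea = "A", oa = "T", eaf = 0.50, beta = 0.10),
              gwas_row("rs_palok", 1e-8, ea = "A", oa = "T", eaf = 0.10, beta = 0.10),
              gwas_row("rs_palfl", 1e-8, ea = "A", oa = "T", eaf = 0.10, beta = 0.10))
  ou <- rbind(gwas_row("rs_same", 0.5, ea = "A", oa = "C", eaf = 0.21, beta = 0.05),
              gwas_row("rs_swap", 0.5, ea = "C", oa = "A", eaf = 0.79, beta = 0.05),
              gwas_row("rs_bad",  0.5, ea = "G", oa = "T", eaf = 0.21, beta = 0.05),
              gwas_row("rs_pal50", 0.5, ea = "A", oa = "T", eaf = 0.50, beta = 0.05),
              gwas_row("rs_palok", 0.5, ea = "A", oa = "T", eaf = 0.12, beta = 0.05),
              gwas_row("rs_palfl", 0.5, ea = "A", oa = "T", eaf = 0.88, beta = 0.05))
  h <- harmonize(ex, ou)
  g <- function(id) h[h$rsid == id, ]
  expect_equal(g("rs_same")$action_taken, "kept")
  expect_equal(g("rs_same")$beta_out, 0.05)
  expect_equal(g("rs_swap")$action_taken, "flipped")
  expect_equal(g("rs_swap")$beta_out, -0.05)
  expect_equal(g("rs_swap")$eaf_out, 0.21)
  expect_equal(g("rs_bad")$action_taken, "dropped")
  expect_equal(g("rs_pal50")$action_taken, "dropped")
  expect_equal(g("rs_palok")$action_taken, "kept")
  # frequencies 0.10 vs 0.88 match only under a flip
  expect_equal(g("rs_palfl")$action_taken, "flipped")
  expect_equal(g("rs_palfl")$beta_out, -0.05)
})

test_that("dropped SNPs remain in the audit table but not in the analysis", {
  ex <- rbind(gwas_row("rs1", 1e-8, ea = "A", oa = "C", beta = 0.1),
              gwas_row("rs2", 1e-8, ea = "A", oa = "G", beta = 0.2))
  ou <- rbind(gwas_row("rs1", 0.5, ea = "T", oa = "G", beta = 0.04),
              gwas_row("rs2", 0.5, ea = "A", oa = "G", beta = 0.08))
  h <- harmonize(ex, ou)
  expect_equal(nrow(h), 2)
  expect_equal(h$action_taken, c("dropped", "kept"))
  expect_match(h$reason[1], "incompatible")
  expect_equal(mr_ivw(h)$n_snps, 1)
})

test_that("confounder screening excludes annotated SNPs from the MR run", {
  ann <- data.frame(rsid = c("rs000001", "rs000002", "rs000003"),
                    trait = c("Hepatitis C virus infection", "height",
                              "Alcohol consumption"))
  drop <- screen_confounders(ann, c("hepatitis", "alcohol"))
  expect_setequal(drop, c("rs000001", "rs000003"))
  gw <- simulate_gwas(gwas_sim_spec(n_snps = 10, theta = 0.3,
                                    palindromic_fraction = 0, seed = 31))
  full <- run_mr(gw$exposure, gw$outcome, gw$ld, n_boot = 50, seed = 1)
  screened <- run_mr(gw$exposure, gw$outcome, gw$ld, n_boot = 50, seed = 1,
                     confounder_snps = drop)
  expect_equal(screened$results$n_snps[1], full$results$n_snps[1] - 2)
})
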