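test_that("Wald ratio follows its first-order definition", {
  h <- make_h(beta_exp = 0.1, beta_out = 0.05, se_out = 0.01)
  r <- wald_ratio(h)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.1)
  h0 <- make_h(beta_exp = 0.2, beta_out = 0, se_out = 0.01)
  r0 <- wald_ratio(h0)
  expect_equal(r0$beta, 0)
  expect_equal(r0$or_, 1.0)
  expect_equal(r0$se, 0.05)
  expect_warning(expect_null(wald_ratio(make_h(0, 0.1))), "beta_exp = 0")
})

test_that("IVW equals the closed-form weighted regression through the origin", {
  h <- make_h(beta_exp = c(0.1, 0.2, 0.3), beta_out = c(0.04, 0.12, 0.15),
              se_out = 0.01)
  r <- mr_ivw(h, random_effects = FALSE)
  expect_equal(r$beta, 0.073 / 0.14, tolerance = 1e-9)
  # single SNP reduces exactly to the Wald ratio
  one <- make_h(0.1, 0.05, se_out = 0.02)
  expect_equal(mr_ivw(one)$beta, wald_ratio(one)$beta)
  expect_equal(mr_ivw(one)$se, wald_ratio(one)$se)
  # homogeneous ratios: Q = 0 and fixed = random effects
  hom <- make_h(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20), se_out = 0.01)
  rf <- mr_ivw(hom, random_effects = FALSE)
  rr <- mr_ivw(hom, random_effects = TRUE)
  expect_equal(rf$beta, 0.5)
  expect_equal(attr(rf, "Q"), 0, tolerance = 1e-20)
  expect_equal(rf$se, rr$se)
  # random-effects se is never below the fixed-effect se
  het <- make_h(c(0.1, 0.2, 0.3), c(0.09, 0.1, 0.02), se_out = 0.01)
  expect_gte(mr_ivw(het, TRUE)$se, mr_ivw(het, FALSE)$se)
})

test_that("Egger regression recovers an exact affine relation", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_h(bx, 0.02 + 0.5 * bx, se_out = 0.05)
  eg <- mr_egger(h)
  expect_equal(eg$intercept, 0.02, tolerance = 1e-10)
  expect_equal(eg$result$beta, 0.5, tolerance = 1e-10)
  # line through the origin: intercept 0, slope = common ratio
  h0 <- make_h(bx, 0.7 * bx, se_out = 0.05)
  eg0 <- mr_egger(h0)
  expect_equal(eg0$intercept, 0, tolerance = 1e-10)
  expect_equal(eg0$result$beta, 0.7, tolerance = 1e-10)
  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("Egger intercept detects planted directional pleiotropy", {
  hits <- vapply(1:150, function(i) {
    gw <- simulate_gwas(gwas_sim_spec(n_snps = 30, theta = 0.2,
                                      invalid_fraction = 1,
                                      pleiotropy_mean = 0.1,
                                      pleiotropy_sd = 0.02,
                                      palindromic_fraction = 0,
                                      seed = 3000 + i))
    h <- harmonize(gw$exposure, gw$outcome)
    mr_egger(h)$intercept_p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)   # far above the 5% null rate
})

test_that("weighted median interpolates the weighted ratio distribution", {
  h <- make_h(c(1, 1, 1), c(0.2, 0.5, 0.9), se_out = 1)
  r <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(r$beta, 0.5)
  # dominant weight pulls the estimate onto that SNP's ratio
  hd <- make_h(c(1, 1, 1), c(0.2, 0.5, 0.9), se_out = c(0.05, 1, 1))
  rd <- mr_weighted_median(hd, n_boot = 50, seed = 1)
  expect_lt(abs(rd$beta - 0.2), 0.05)
  expect_error(mr_weighted_median(make_h(1, 1)), "at least 3")
})

test_that("weighted median resists a wild outlier among concordant ratios", {
  set.seed(4)
  bx <- runif(10, 0.08, 0.12)
  ratios <- c(rep(0.5, 9), 5)
  h <- make_h(bx, ratios * bx, se_exp = 0.001, se_out = 0.02)
  r <- mr_weighted_median(h, n_boot = 300, seed = 2)
  expect_lt(abs(r$beta - 0.5), 2 * r$se)
  expect_lt(abs(r$beta - 0.5), 0.1)
})

test_that("mode estimators find the majority cluster and honor weights", {
  # bimodal ratios: 7 near 0.5, 3 near 2.0
  bx <- rep(0.1, 10)
  ratios <- c(0.48, 0.49, 0.5, 0.5, 0.51, 0.52, 0.5, 1.98, 2.0, 2.02)
  h <- make_h(bx, ratios * bx, se_exp = 1e-4, se_out = 0.01)
  m <- mr_mode(h, n_boot = 100, seed = 3)
  simple <- m[m$method == "simple_mode", ]
  expect_lt(abs(simple$beta - 0.5), 0.1)
  # weights inflating the minority cluster flip the weighted mode
  se_out <- c(rep(0.2, 7), rep(0.001, 3))
  hw <- make_h(bx, ratios * bx, se_exp = 1e-4, se_out = se_out)
  mw <- mr_mode(hw, n_boot = 100, seed = 3)
  expect_lt(abs(mw$beta[mw$method == "weighted_mode"] - 2.0), 0.1)
  # zero spread collapses to the common ratio with zero se
  hz <- make_h(c(0.1, 0.2, 0.3), 0.6 * c(0.1, 0.2, 0.3))
  mz <- mr_mode(hz, n_boot = 10, seed = 1)
  expect_equal(mz$beta, c(0.6, 0.6))
  expect_equal(mz$se, c(0, 0))
})

test_that("all estimators are invariant to joint allele reorientation", {
  gw <- simulate_gwas(gwas_sim_spec(n_snps = 12, theta = 0.3,
                                    palindromic_fraction = 0, seed = 44))
  h <- harmonize(gw$exposure, gw$outcome)
  h2 <- h
  flip <- c(2, 5, 7)
  h2$beta_exp[flip] <- -h2$beta_exp[flip]
  h2$beta_out[flip] <- -h2$beta_out[flip]
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h)$beta, tolerance = 1e-10)
  expect_equal(mr_egger(h2)$result$beta, mr_egger(h)$result$beta,
               tolerance = 1e-10)
  expect_equal(mr_weighted_median(h2, 50, 9)$beta,
               mr_weighted_median(h, 50, 9)$beta, tolerance = 1e-10)
  m1 <- mr_mode(h, n_boot = 20, seed = 9)
  m2 <- mr_mode(h2, n_boot = 20, seed = 9)
  expect_equal(m2$beta, m1$beta, tolerance = 1e-10)
})

test_that("second-order Wald se and t-quantile IVW options behave", {
  h <- make_h(0.1, 0.05, se_exp = 0.02, se_out = 0.01)
  first <- wald_ratio(h)
  second <- wald_ratio(h, second_order = TRUE)
  expect_gt(second$se, first$se)
  expect_equal(second$se,
               sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.02^2 / 0.1^4))
  hh <- make_h(c(0.1, 0.2, 0.3), c(0.04, 0.12, 0.15), se_out = 0.01)
  expect_gt(mr_ivw(hh, use_t = TRUE)$p, mr_ivw(hh, use_t = FALSE)$p)
  expect_equal(mr_ivw(hh, use_t = TRUE)$beta, mr_ivw(hh)$beta)
})
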