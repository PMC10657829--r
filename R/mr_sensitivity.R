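#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (theta_j - theta_ivw_fixed)^2` over the per-SNP Wald
#' ratios, with first-order weights `w_j = (beta_exp_j / se_out_j)^2`; the
#' p-value is the upper chi-square tail with `n - 1` degrees of freedom.
#'
#' @param snps harmonized table (>= 2 usable SNPs).
#' @return list: `Q`, `df`, `p`.
#' @export
cochran_q <- function(snps) {
  h <- usable(snps)
  stopifnot(nrow(h) >= 2)
  theta <- h$beta_out / h$beta_exp
  w <- (h$beta_exp / h$se_out)^2
  theta_fixed <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - theta_fixed)^2)
  list(Q = q, df = nrow(h) - 1, p = stats::pchisq(q, nrow(h) - 1, lower.tail = FALSE))
}

#' MR-PRESSO: global pleiotropy, outlier, and distortion tests
#'
#' Global test: the observed leave-one-out residual sum of squares of the
#' IVW fit is compared with its null distribution, obtained by simulating
#' summary statistics under the fitted no-pleiotropy model
#' (`beta_out* ~ N(theta_{-j} beta_exp*, se_out)`). Outlier test: each SNP's
#' observed squared residual against its simulated distribution, Bonferroni
#' corrected at `alpha`. Distortion test: the relative change in the IVW
#' estimate after removing flagged outliers, against the distribution of
#' changes from removing random subsets of the same size.
#'
#' @param snps harmonized table (>= 4 usable SNPs).
#' @param n_sim simulated datasets for the null (default 1000).
#' @param seed RNG seed.
#' @param alpha significance level for the outlier test (Bonferroni across
#'   SNPs; default 0.05).
#' @return list: `global_rss`, `global_p`, `outliers` (rsids),
#'   `outlier_p` (per-SNP, Bonferroni-adjusted), `distortion_p` (NA when no
#'   outlier is flagged).
#' @export
mr_presso <- function(snps, n_sim = 1000, seed = 1L, alpha = 0.05) {
  h <- usable(snps)
  m <- nrow(h)
  if (m < 4) stop("MR-PRESSO requires at least 4 SNPs, got ", m)
  w <- 1 / h$se_out^2
  theta_loo <- vapply(seq_len(m), function(j) {
    hh <- h[-j, ]
    ww <- w[-j]
    sum(ww * hh$beta_exp * hh$beta_out) / sum(ww * hh$beta_exp^2)
  }, numeric(1))
  obs_res2 <- (h$beta_out - theta_loo * h$beta_exp)^2
  rss_obs <- sum(obs_res2)

  sim <- with_seed(seed, {
    # null: outcome betas regenerated under the per-SNP leave-one-out fit
    bx <- matrix(stats::rnorm(n_sim * m, rep(h$beta_exp, each = n_sim),
                              rep(h$se_exp, each = n_sim)), n_sim, m)
    by <- matrix(stats::rnorm(n_sim * m,
                              sweep(bx, 2, theta_loo, `*`),
                              rep(h$se_out, each = n_sim)), n_sim, m)
    res2 <- matrix(0, n_sim, m)
    rss <- numeric(n_sim)
    for (s in seq_len(n_sim)) {
      tl <- vapply(seq_len(m), function(j) {
        ww <- w[-j]
        sum(ww * bx[s, -j] * by[s, -j]) / sum(ww * bx[s, -j]^2)
      }, numeric(1))
      res2[s, ] <- (by[s, ] - tl * bx[s, ])^2
      rss[s] <- sum(res2[s, ])
    }
    list(res2 = res2, rss = rss)
  })
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (1 + n_sim)

  out_p_raw <- vapply(seq_len(m), function(j)
    (1 + sum(sim$res2[, j] >= obs_res2[j])) / (1 + n_sim), numeric(1))
  out_p <- pmin(1, out_p_raw * m)
  outliers <- h$rsid[out_p < alpha]

  distortion_p <- NA_real_
  if (length(outliers) > 0 && length(outliers) < m - 1) {
    ivw_beta <- function(idx) {
      sum(w[idx] * h$beta_exp[idx] * h$beta_out[idx]) /
        sum(w[idx] * h$beta_exp[idx]^2)
    }
    full <- ivw_beta(seq_len(m))
    clean <- ivw_beta(which(!h$rsid %in% outliers))
    d_obs <- (full - clean) / abs(clean)
    d_null <- with_seed(seed + 1L, {
      vapply(seq_len(n_sim), function(s) {
        drop_idx <- sample.int(m, length(outliers))
        sub <- ivw_beta(setdiff(seq_len(m), drop_idx))
        (full - sub) / abs(sub)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (1 + n_sim)
  }
  list(global_rss = rss_obs, global_p = global_p,
       outliers = outliers, outlier_p = stats::setNames(out_p, h$rsid),
       distortion_p = distortion_p)
}

#' Steiger directionality test
#'
#' Per-SNP variance explained from the squared-z statistic via
#' `r2 = F / (F + n - 2)` with `F = (beta / se)^2`, summed over instruments
#' on each side. The causal direction is exposure -> outcome when the
#' exposure r-squared exceeds the outcome r-squared; the p-value compares
#' the two correlations with the z-test on Fisher-transformed values from
#' independent samples.
#'
#' @param snps harmonized table.
#' @param n_exp,n_out GWAS sample sizes; default to the harmonized table's
#'   `n_exp` / `n_out` columns.
#' @return list: `direction` (TRUE = exposure causes outcome),
#'   `r2_exposure`, `r2_outcome`, `p`, `indeterminate` (TRUE when the two
#'   sides are indistinguishable).
#' @export
mr_steiger <- function(snps, n_exp = NULL, n_out = NULL) {
  h <- usable(snps)
  n_exp <- n_exp %||% h$n_exp[1]
  n_out <- n_out %||% h$n_out[1]
  if (is.na(n_exp) || is.na(n_out) || n_exp <= 2 || n_out <= 2)
    stop("Steiger test needs sample sizes > 2 on both sides")
  f_exp <- (h$beta_exp / h$se_exp)^2
  f_out <- (h$beta_out / h$se_out)^2
  r2_exp <- sum(f_exp / (f_exp + n_exp - 2))
  r2_out <- sum(f_out / (f_out + n_out - 2))
  r_exp <- sqrt(min(r2_exp, 1))
  r_out <- sqrt(min(r2_out, 1))
  z <- (atanh(r_exp) - atanh(r_out)) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(direction = r2_exp > r2_out, r2_exposure = r2_exp, r2_outcome = r2_out,
       p = p, indeterminate = abs(r2_exp - r2_out) < .Machine$double.eps^0.5)
}
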