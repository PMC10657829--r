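# Causal estimators for two-sample MR. All take the harmonized table
# (columns beta_exp, se_exp, beta_out, se_out) restricted to usable SNPs.

mr_result <- function(method, beta, se, n_snps, p = NULL) {
  p <- p %||% (2 * stats::pnorm(-abs(beta / se)))
  data.frame(method = method, beta = beta, se = se,
             or_ = exp(beta),
             ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
             p = p, n_snps = n_snps, stringsAsFactors = FALSE)
}

usable <- function(h) {
  if (!is.null(h$action_taken)) h <- h[h$action_taken != "dropped", , drop = FALSE]
  h
}

#' Wald ratio for a single instrument
#'
#' `beta = beta_out / beta_exp` with the first-order standard error
#' `se = se_out / |beta_exp|`.
#'
#' @param snp one harmonized row.
#' @param second_order logical; `TRUE` adds the exposure-uncertainty term
#'   `beta_out^2 se_exp^2 / beta_exp^4` to the variance (delta method).
#' @return One-row MR result data.frame.
#' @export
wald_ratio <- function(snp, second_order = FALSE) {
  stopifnot(nrow(snp) == 1)
  if (snp$beta_exp == 0) {
    warning("beta_exp = 0: Wald ratio undefined, SNP skipped")
    return(NULL)
  }
  se <- if (second_order) {
    sqrt(snp$se_out^2 / snp$beta_exp^2 +
           snp$beta_out^2 * snp$se_exp^2 / snp$beta_exp^4)
  } else {
    snp$se_out / abs(snp$beta_exp)
  }
  mr_result("wald", snp$beta_out / snp$beta_exp, se, 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of the outcome betas on the exposure betas through
#' the origin with weights `1 / se_out^2`. The random-effects variant uses
#' the multiplicative over-dispersion model: the fixed-effect standard error
#' is inflated by `sqrt(max(1, Q / (n - 1)))` and never deflated. A single
#' SNP reduces exactly to the Wald ratio.
#'
#' @param snps harmonized table.
#' @param random_effects logical (default `TRUE`, the primary analysis).
#' @param use_t logical; `FALSE` (default) takes the p-value from the normal
#'   distribution, `TRUE` from a t with `n_snps - 1` degrees of freedom.
#' @return One-row MR result data.frame with attribute `Q`.
#' @export
mr_ivw <- function(snps, random_effects = TRUE, use_t = FALSE) {
  h <- usable(snps)
  stopifnot(nrow(h) >= 1)
  if (nrow(h) == 1) {
    out <- wald_ratio(h)
    out$method <- "ivw"
    attr(out, "Q") <- 0
    return(out)
  }
  w <- 1 / h$se_out^2
  beta <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  se_fixed <- sqrt(1 / sum(w * h$beta_exp^2))
  q <- sum(w * (h$beta_out - beta * h$beta_exp)^2)
  se <- if (random_effects) se_fixed * sqrt(max(1, q / (nrow(h) - 1))) else se_fixed
  p <- if (use_t) 2 * stats::pt(-abs(beta / se), nrow(h) - 1) else NULL
  out <- mr_result("ivw", beta, se, nrow(h), p = p)
  attr(out, "Q") <- q
  out
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure betas *with* an intercept
#' (weights `1 / se_out^2`) after orienting every SNP so `beta_exp >= 0`.
#' The slope is the pleiotropy-adjusted causal estimate; a nonzero intercept
#' indicates directional pleiotropy. Standard errors use the multiplicative
#' over-dispersion model (residual variance floored at 1).
#'
#' @param snps harmonized table (needs at least 3 SNPs).
#' @return list: `result` (one-row MR result), `intercept`, `intercept_se`,
#'   `intercept_p`.
#' @export
mr_egger <- function(snps) {
  h <- usable(snps)
  if (nrow(h) < 3) stop("MR-Egger requires at least 3 SNPs, got ", nrow(h))
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  x <- h$beta_exp * flip
  y <- h$beta_out * flip
  w <- 1 / h$se_out^2
  X <- cbind(1, x)
  xtwx_inv <- solve(crossprod(X, w * X))
  coefs <- drop(xtwx_inv %*% crossprod(X, w * y))
  df <- nrow(h) - 2
  resid <- y - drop(X %*% coefs)
  phi <- max(1, sum(w * resid^2) / df)  # multiplicative model, never < 1
  ses <- sqrt(diag(xtwx_inv) * phi)
  int <- unname(coefs[1]); slope <- unname(coefs[2])
  int_se <- unname(ses[1]); slope_se <- unname(ses[2])
  res <- mr_result("egger", slope, slope_se, nrow(h),
                   p = 2 * stats::pt(-abs(slope / slope_se), df))
  list(result = res, intercept = int, intercept_se = int_se,
       intercept_p = 2 * stats::pt(-abs(int / int_se), df))
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  # standardized cumulative weights: midpoints of the cumulative sum
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Orders the per-SNP Wald ratios and interpolates the inverse-variance
#' weighted cumulative distribution at 0.5; consistent when at least half
#' the weight comes from valid instruments. Standard error by parametric
#' bootstrap of the summary statistics.
#'
#' @param snps harmonized table (>= 3 SNPs).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed.
#' @return One-row MR result data.frame.
#' @export
mr_weighted_median <- function(snps, n_boot = 1000, seed = 1L) {
  h <- usable(snps)
  if (nrow(h) < 3) stop("weighted median requires at least 3 SNPs, got ", nrow(h))
  ratios <- h$beta_out / h$beta_exp
  w <- 1 / (h$se_out / abs(h$beta_exp))^2
  est <- weighted_median_point(ratios, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(h), h$beta_exp, h$se_exp)
      by <- stats::rnorm(nrow(h), h$beta_out, h$se_out)
      rb <- by / bx
      wb <- 1 / (h$se_out / abs(bx))^2
      weighted_median_point(rb, wb)
    }, numeric(1))
  })
  mr_result("weighted_median", est, stats::sd(boots), nrow(h))
}

silverman_bw <- function(ratios, weights = NULL) {
  n <- length(ratios)
  s <- stats::sd(ratios)
  m <- stats::mad(ratios)
  spread <- if (m > 0) min(s, m) else s
  0.9 * spread * n^(-1 / 5)
}

mode_point <- function(ratios, weights, bw) {
  if (bw <= 0 || stats::sd(ratios) == 0) return(ratios[1])
  grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw, length.out = 512)
  w <- weights / sum(weights)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm((g - ratios) / bw)), numeric(1))
  grid[which.max(dens)]
}

#' Simple- and weighted-mode estimators
#'
#' Gaussian-kernel density over the per-SNP Wald ratios — unweighted for the
#' simple mode, inverse-variance weighted for the weighted mode — with
#' bandwidth `bandwidth_factor` times the modified Silverman rule
#' `0.9 * min(sd, mad) * n^(-1/5)`. The estimate is the density argmax;
#' standard errors by parametric bootstrap. Zero ratio spread collapses to
#' the common ratio with zero standard error.
#'
#' @param snps harmonized table (>= 3 SNPs).
#' @param bandwidth_factor multiplier on the Silverman bandwidth (default 1).
#' @param n_boot bootstrap draws.
#' @param seed RNG seed.
#' @return Two-row MR result data.frame (`simple_mode`, `weighted_mode`).
#' @export
mr_mode <- function(snps, bandwidth_factor = 1, n_boot = 1000, seed = 1L) {
  h <- usable(snps)
  if (nrow(h) < 3) stop("mode estimators require at least 3 SNPs, got ", nrow(h))
  ratios <- h$beta_out / h$beta_exp
  w_iv <- 1 / (h$se_out / abs(h$beta_exp))^2
  if (stats::sd(ratios) == 0) {
    return(rbind(mr_result("simple_mode", ratios[1], 0, nrow(h), p = 0),
                 mr_result("weighted_mode", ratios[1], 0, nrow(h), p = 0)))
  }
  bw <- bandwidth_factor * silverman_bw(ratios)
  est_s <- mode_point(ratios, rep(1, nrow(h)), bw)
  est_w <- mode_point(ratios, w_iv, bw)
  boots <- with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(nrow(h), h$beta_exp, h$se_exp)
      by <- stats::rnorm(nrow(h), h$beta_out, h$se_out)
      rb <- by / bx
      wb <- 1 / (h$se_out / abs(bx))^2
      bwb <- bandwidth_factor * silverman_bw(rb)
      if (bwb <= 0) return(c(rb[1], rb[1]))
      c(mode_point(rb, rep(1, length(rb)), bwb), mode_point(rb, wb, bwb))
    }, numeric(2)))
  })
  rbind(mr_result("simple_mode", est_s, stats::sd(boots[, 1]), nrow(h)),
        mr_result("weighted_mode", est_w, stats::sd(boots[, 2]), nrow(h)))
}
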