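#' Run the complete two-sample MR analysis for one exposure
#'
#' Composes instrument selection, harmonization, the five causal estimators
#' (IVW as the primary analysis, MR-Egger, weighted median, simple and
#' weighted mode; the Wald ratio when a single instrument remains) and the
#' sensitivity diagnostics (Cochran's Q, MR-Egger intercept, MR-PRESSO when
#' at least four SNPs are usable, Steiger directionality).
#'
#' @param exposure,outcome GWAS summary data.frames.
#' @param ld r-squared lookup passed to [select_instruments()].
#' @param cfg an [iv_config()].
#' @param exposure_name label carried into the output tables.
#' @param n_boot bootstrap draws for median/mode standard errors.
#' @param seed RNG seed for all stochastic diagnostics.
#' @param confounder_snps optional rsids associated with confounder traits
#'   (e.g. from a SNP->trait annotation join); excluded before analysis.
#' @return list: `results` (forest-style data.frame: method, n_snps, beta,
#'   se, OR, CI, p), `sensitivity` (Q, Egger intercept, PRESSO, Steiger,
#'   sign-disagreement flag), `harmonized`, `instruments`, `status`.
#' @export
run_mr <- function(exposure, outcome, ld = NULL, cfg = iv_config(),
                   exposure_name = "exposure", n_boot = 1000, seed = 1L,
                   confounder_snps = NULL) {
  iv <- select_instruments(exposure, ld, cfg)
  if (!is.null(confounder_snps))
    iv <- iv[!iv$rsid %in% confounder_snps, , drop = FALSE]
  if (nrow(iv) == 0)
    return(list(results = NULL, sensitivity = NULL, harmonized = NULL,
                instruments = iv, status = "no valid instruments",
                exposure = exposure_name))
  h <- harmonize(iv, outcome)
  hu <- usable(h)
  if (nrow(hu) == 0)
    return(list(results = NULL, sensitivity = NULL, harmonized = h,
                instruments = iv, status = "no valid instruments",
                exposure = exposure_name))

  res <- list(mr_ivw(hu, random_effects = TRUE))
  sens <- list(egger_intercept = NA_real_, egger_intercept_se = NA_real_,
               egger_intercept_p = NA_real_,
               cochran_q = NA_real_, q_df = NA_integer_, q_p = NA_real_,
               presso_global_p = NA_real_, presso_outliers = character(0),
               presso_distortion_p = NA_real_,
               steiger_direction = NA, steiger_p = NA_real_,
               sign_disagreement = FALSE)
  if (nrow(hu) == 1) {
    res <- c(list(wald_ratio(hu)), res)
  }
  if (nrow(hu) >= 2) {
    q <- cochran_q(hu)
    sens$cochran_q <- q$Q; sens$q_df <- q$df; sens$q_p <- q$p
  }
  if (nrow(hu) >= 3) {
    eg <- mr_egger(hu)
    res <- c(res, list(eg$result,
                       mr_weighted_median(hu, n_boot, child_seed(seed, "median")),
                       mr_mode(hu, 1, n_boot, child_seed(seed, "mode"))))
    sens$egger_intercept <- eg$intercept
    sens$egger_intercept_se <- eg$intercept_se
    sens$egger_intercept_p <- eg$intercept_p
  }
  if (nrow(hu) >= 4) {
    pr <- mr_presso(hu, n_sim = n_boot, seed = child_seed(seed, "presso"))
    sens$presso_global_p <- pr$global_p
    sens$presso_outliers <- pr$outliers
    sens$presso_distortion_p <- pr$distortion_p
  }
  st <- try(mr_steiger(hu), silent = TRUE)
  if (!inherits(st, "try-error")) {
    sens$steiger_direction <- st$direction
    sens$steiger_p <- st$p
  }
  results <- do.call(rbind, res)
  results <- cbind(exposure = exposure_name, results)
  sens$sign_disagreement <- length(unique(sign(results$beta[results$beta != 0]))) > 1
  list(results = results, sensitivity = sens, harmonized = h,
       instruments = iv, status = "ok", exposure = exposure_name)
}

#' Forest-style summary table across exposures
#'
#' Stacks per-exposure MR results into the layout of a forest plot: method,
#' number of SNPs, OR with 95 percent CI, p-value, heterogeneity p and
#' Egger-intercept p.
#'
#' @param runs list of [run_mr()] outputs.
#' @return data.frame, one row per (exposure, method); exposures with no
#'   valid instruments appear as a single status row.
#' @export
mr_forest_table <- function(runs) {
  rows <- lapply(runs, function(r) {
    if (is.null(r$results))
      return(data.frame(exposure = r$exposure, method = r$status,
                        n_snps = 0L, beta = NA_real_, se = NA_real_,
                        or_ = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, q_p = NA_real_,
                        egger_intercept_p = NA_real_,
                        stringsAsFactors = FALSE))
    cbind(r$results[, c("exposure", "method", "n_snps", "beta", "se",
                        "or_", "ci_low", "ci_high", "p")],
          q_p = r$sensitivity$q_p,
          egger_intercept_p = r$sensitivity$egger_intercept_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
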