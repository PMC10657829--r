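#' Specification for simulated two-sample GWAS summary statistics
#'
#' Encodes the linear causal model `b_out = theta * b_exp + alpha + eps`:
#' valid instruments carry no pleiotropy (`alpha = 0`); a configurable
#' fraction are invalid and draw `alpha` from a normal whose nonzero mean
#' creates directional pleiotropy. Standard errors follow the standard
#' summary-statistic approximation `se = 1 / sqrt(2 * maf * (1 - maf) * n)`.
#'
#' @param n_snps number of variants.
#' @param theta true causal effect on the log-odds / beta scale.
#' @param invalid_fraction fraction of instruments with pleiotropy.
#' @param pleiotropy_mean,pleiotropy_sd normal parameters for the pleiotropy
#'   term of invalid instruments; a nonzero mean is directional pleiotropy.
#' @param exposure_beta_dist `c(mean, sd)` of true per-allele exposure effects.
#' @param n_exposure,n_outcome GWAS sample sizes (defaults mirror a
#'   16S-microbiome meta-analysis of 18,340 and a biobank outcome of
#'   3,970 cases + 373,307 controls).
#' @param outcome_cases number of cases when the outcome is binary, or `NULL`
#'   for a quantitative outcome. For a case-control GWAS the per-SNP
#'   standard error uses the effective sample size
#'   `n_cases * n_controls / n` (the log-odds-scale analogue of the
#'   quantitative-trait formula); the reported `n` column stays the total.
#' @param ld_blocks list of `c(size, r2)` pairs; SNPs are grouped into
#'   consecutive blocks sharing the stated within-block r-squared.
#' @param maf_range interval in (0, 0.5] for the uniform minor-allele
#'   frequency draw.
#' @param flip_fraction fraction of SNPs whose outcome record is reported on
#'   the opposite allele (exercises harmonization).
#' @param palindromic_fraction fraction of A/T or C/G variants.
#' @param measurement_noise logical; `FALSE` suppresses the sampling noise on
#'   observed betas (the noise-free limit used in exactness tests).
#' @param seed integer root seed.
#' @return An object of class `gwas_sim_spec`.
#' @export
gwas_sim_spec <- function(n_snps = 30L,
                          theta = 0,
                          invalid_fraction = 0,
                          pleiotropy_mean = 0,
                          pleiotropy_sd = 0,
                          exposure_beta_dist = c(0.08, 0.02),
                          n_exposure = 18340L,
                          n_outcome = 377277L,
                          outcome_cases = 3970L,
                          ld_blocks = list(),
                          maf_range = c(0.05, 0.5),
                          flip_fraction = 0.2,
                          palindromic_fraction = 0.1,
                          measurement_noise = TRUE,
                          seed = 1L) {
  stopifnot(n_snps >= 1, n_exposure > 0, n_outcome > 0)
  stopifnot(invalid_fraction >= 0, invalid_fraction <= 1, pleiotropy_sd >= 0)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5)
  n_invalid <- invalid_fraction * n_snps
  if (abs(n_invalid - round(n_invalid)) > 1e-8)
    stop("invalid_fraction * n_snps must be an integer count")
  if (!is.null(outcome_cases))
    stopifnot(outcome_cases > 0, outcome_cases < n_outcome)
  structure(list(n_snps = as.integer(n_snps), theta = theta,
                 invalid_fraction = invalid_fraction,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 exposure_beta_dist = exposure_beta_dist,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 outcome_cases = outcome_cases,
                 ld_blocks = ld_blocks, maf_range = maf_range,
                 flip_fraction = flip_fraction,
                 palindromic_fraction = palindromic_fraction,
                 measurement_noise = isTRUE(measurement_noise),
                 seed = as.integer(seed)),
            class = "gwas_sim_spec")
}

#' Simulate exposure and outcome GWAS summary tables
#'
#' @param spec a [gwas_sim_spec()].
#' @return A list with `exposure` and `outcome` data.frames in the standard
#'   summary-statistic layout (`rsid`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n`), an `ld` r-squared matrix
#'   keyed by rsid, and `truth` (per-SNP true effects, pleiotropy terms and
#'   validity flags).
#' @export
simulate_gwas <- function(spec) {
  stopifnot(inherits(spec, "gwas_sim_spec"))
  with_seed(child_seed(spec$seed, "gwas"), {
    m <- spec$n_snps
    rsid <- sprintf("rs%06d", seq_len(m))

    # genomic layout: LD blocks are placed close together on one chromosome,
    # everything else far apart so clumping sees them as independent
    chrom <- rep(1L, m)
    pos <- seq_len(m) * 1e6
    ld <- diag(1, m)
    dimnames(ld) <- list(rsid, rsid)
    idx <- 1L
    for (b in spec$ld_blocks) {
      size <- as.integer(b[1]); r2 <- b[2]
      if (idx + size - 1L > m) stop("ld_blocks exceed n_snps")
      span <- idx:(idx + size - 1L)
      ld[span, span] <- r2
      diag(ld)[span] <- 1  # no-op, kept for clarity
      ld[cbind(span, span)] <- 1
      pos[span] <- pos[idx] + (seq_len(size) - 1L) * 1e4
      idx <- idx + size
    }

    maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
    n_out_eff <- if (is.null(spec$outcome_cases)) spec$n_outcome else
      spec$outcome_cases * (spec$n_outcome - spec$outcome_cases) / spec$n_outcome
    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * spec$n_exposure)
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * n_out_eff)

    b_exp <- stats::rnorm(m, spec$exposure_beta_dist[1], spec$exposure_beta_dist[2])
    n_invalid <- as.integer(round(spec$invalid_fraction * m))
    invalid <- rep(FALSE, m)
    if (n_invalid > 0) invalid[sample.int(m, n_invalid)] <- TRUE
    alpha <- ifelse(invalid,
                    stats::rnorm(m, spec$pleiotropy_mean, spec$pleiotropy_sd), 0)
    b_out <- spec$theta * b_exp + alpha

    if (spec$measurement_noise) {
      beta_exp_hat <- stats::rnorm(m, b_exp, se_exp)
      beta_out_hat <- stats::rnorm(m, b_out, se_out)
    } else {
      beta_exp_hat <- b_exp
      beta_out_hat <- b_out
    }

    # allele pairs; a configurable fraction are palindromic (A/T or C/G)
    pal <- stats::runif(m) < spec$palindromic_fraction
    pairs <- matrix(NA_character_, m, 2)
    for (i in seq_len(m)) {
      if (pal[i]) {
        pairs[i, ] <- if (stats::runif(1) < 0.5) c("A", "T") else c("C", "G")
      } else {
        repeat {
          a <- sample(c("A", "C", "G", "T"), 2)
          if (!identical(sort(a), c("A", "T")) && !identical(sort(a), c("C", "G"))) break
        }
        pairs[i, ] <- a
      }
    }

    p2 <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))
    exposure <- data.frame(
      rsid = rsid, chrom = chrom, pos = pos,
      effect_allele = pairs[, 1], other_allele = pairs[, 2],
      eaf = maf, beta = beta_exp_hat, se = se_exp,
      p = p2(beta_exp_hat, se_exp), n = spec$n_exposure,
      stringsAsFactors = FALSE)

    flip <- stats::runif(m) < spec$flip_fraction
    outcome <- data.frame(
      rsid = rsid, chrom = chrom, pos = pos,
      effect_allele = ifelse(flip, pairs[, 2], pairs[, 1]),
      other_allele  = ifelse(flip, pairs[, 1], pairs[, 2]),
      eaf = ifelse(flip, 1 - maf, maf),
      beta = ifelse(flip, -beta_out_hat, beta_out_hat),
      se = se_out, p = p2(beta_out_hat, se_out), n = spec$n_outcome,
      stringsAsFactors = FALSE)

    list(exposure = exposure, outcome = outcome, ld = ld,
         truth = data.frame(rsid = rsid, b_exp = b_exp, b_out = b_out,
                            alpha = alpha, invalid = invalid, flipped = flip,
                            palindromic = pal, stringsAsFactors = FALSE))
  })
}
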