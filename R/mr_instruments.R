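#' Instrument-selection configuration
#'
#' Defaults follow common practice for microbiome exposures: a relaxed
#' genome-wide threshold `P < 1e-5` (few 16S abundance loci reach 5e-8),
#' clumping at 500 kb / r-squared 0.1, and per-SNP strength `F > 10` with
#' the squared-z approximation `F = (beta / se)^2`.
#'
#' @param p_threshold association p-value cutoff for the exposure.
#' @param clump_window clumping window in base pairs.
#' @param clump_r2 r-squared above which a SNP is clumped away.
#' @param f_min minimum instrument F-statistic.
#' @return list of class `iv_config`.
#' @export
iv_config <- function(p_threshold = 1e-5, clump_window = 5e5,
                      clump_r2 = 0.1, f_min = 10) {
  stopifnot(p_threshold > 0, clump_window > 0, clump_r2 > 0, f_min > 0)
  structure(list(p_threshold = p_threshold, clump_window = clump_window,
                 clump_r2 = clump_r2, f_min = f_min), class = "iv_config")
}

ld_lookup <- function(ld, a, b) {
  if (is.null(ld)) return(0)
  if (is.matrix(ld)) {
    if (a %in% rownames(ld) && b %in% colnames(ld)) return(ld[a, b])
    return(0)
  }
  hit <- (ld$rsid_a == a & ld$rsid_b == b) | (ld$rsid_a == b & ld$rsid_b == a)
  if (any(hit)) ld$r2[which(hit)[1]] else 0
}

#' Select instrumental variables from an exposure GWAS
#'
#' Three screens in order: (1) association `p < p_threshold`; (2) greedy LD
#' clumping — SNPs are swept by ascending p and one is retained unless it
#' lies within `clump_window` of an already-retained SNP on the same
#' chromosome with `r2 > clump_r2` (pairs absent from the LD input are
#' treated as independent); (3) instrument strength `F = (beta/se)^2 >
#' f_min`.
#'
#' @param exposure GWAS summary data.frame (`rsid`, `chrom`, `pos`, `beta`,
#'   `se`, `p`, ...).
#' @param ld r-squared lookup: a matrix keyed by rsid, a data.frame
#'   (`rsid_a`, `rsid_b`, `r2`), or `NULL` for fully independent SNPs.
#' @param cfg an [iv_config()].
#' @return The retained exposure rows with an added `F_stat` column; zero
#'   rows (with attribute `reason = "no valid instruments"`) when nothing
#'   survives — an explicit outcome, not an error.
#' @export
select_instruments <- function(exposure, ld = NULL, cfg = iv_config()) {
  x <- exposure[exposure$p < cfg$p_threshold, , drop = FALSE]
  x <- x[order(x$p), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(x))) {
    clumped <- FALSE
    for (j in kept) {
      if (x$chrom[i] == x$chrom[j] &&
          abs(x$pos[i] - x$pos[j]) <= cfg$clump_window &&
          ld_lookup(ld, x$rsid[i], x$rsid[j]) > cfg$clump_r2) {
        clumped <- TRUE
        break
      }
    }
    if (!clumped) kept <- c(kept, i)
  }
  x <- x[kept, , drop = FALSE]
  x$F_stat <- (x$beta / x$se)^2
  x <- x[x$F_stat > cfg$f_min, , drop = FALSE]
  rownames(x) <- NULL
  if (nrow(x) == 0) attr(x, "reason") <- "no valid instruments"
  x
}

#' Screen instruments against confounder-trait associations
#'
#' Joins a user-supplied SNP-to-trait annotation table (e.g. a pre-fetched
#' phenome-scan export) against an exclusion trait list and returns the
#' rsids to drop, so variants associated with known confounders (hepatitis
#' A/C, alcohol use, autoimmune liver disease, ...) never enter the
#' analysis. Matching is case-insensitive substring on the trait name.
#'
#' @param annotation data.frame with columns `rsid`, `trait`.
#' @param exclude_traits character vector of confounder trait names.
#' @return Character vector of rsids to exclude (possibly empty), suitable
#'   for [run_mr()]'s `confounder_snps` argument.
#' @export
screen_confounders <- function(annotation, exclude_traits) {
  stopifnot(all(c("rsid", "trait") %in% names(annotation)))
  hit <- Reduce(`|`, lapply(exclude_traits, function(tr)
    grepl(tr, annotation$trait, ignore.case = TRUE)), rep(FALSE, nrow(annotation)))
  unique(annotation$rsid[hit])
}

is_palindromic <- function(a1, a2) {
  p <- paste(pmin(a1, a2), pmax(a1, a2))
  p %in% c("A T", "C G")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Joins on rsid and aligns the outcome to the exposure's effect allele:
#' matching alleles are kept; swapped alleles flip the outcome beta sign and
#' allele frequency; allele pairs that match neither way (including
#' cross-strand reports) are dropped as incompatible.
#' Palindromic (A/T, C/G) variants are resolved by allele
#' frequency when both frequencies are outside the ambiguity zone
#' `(limit, 1 - limit)`, and dropped otherwise. Incompatible allele sets are
#' dropped with a reason.
#'
#' @param exposure,outcome GWAS summary data.frames.
#' @param palindrome_eaf_limit ambiguity bound (default 0.42: frequencies in
#'   (0.42, 0.58) are uninformative about strand).
#' @return data.frame `rsid`, `beta_exp`, `se_exp`, `beta_out`, `se_out`,
#'   `eaf_exp`, `eaf_out`, `palindromic`, `action_taken` (kept / flipped /
#'   dropped), `reason`; dropped SNPs stay in the table for audit, and the
#'   usable subset is `action_taken != "dropped"`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  common <- intersect(exposure$rsid, outcome$rsid)
  ex <- exposure[match(common, exposure$rsid), ]
  ou <- outcome[match(common, outcome$rsid), ]
  n <- length(common)
  action <- character(n); reason <- character(n)
  beta_out <- ou$beta; eaf_out <- ou$eaf
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  for (i in seq_len(n)) {
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    if (pal[i]) {
      # allele labels cannot distinguish strands; resolve by frequency
      if (!setequal(c(e1, e2), c(o1, o2))) {
        action[i] <- "dropped"; reason[i] <- "incompatible alleles"; next
      }
      fe <- ex$eaf[i]; fo <- ou$eaf[i]
      lo <- palindrome_eaf_limit; hi <- 1 - palindrome_eaf_limit
      if (is.na(fe) || is.na(fo) || (fe > lo && fe < hi) || (fo > lo && fo < hi)) {
        action[i] <- "dropped"; reason[i] <- "palindromic, ambiguous frequency"
        next
      }
      if ((fe < 0.5) == (fo < 0.5)) {
        action[i] <- "kept"
      } else {
        beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]
        action[i] <- "flipped"
      }
    } else if (o1 == e1 && o2 == e2) {
      action[i] <- "kept"
    } else if (o1 == e2 && o2 == e1) {
      beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "flipped"
    } else {
      # includes cross-strand reports (e.g. A/C vs G/T): without a strand
      # reference these are ambiguous, so they are dropped, not inferred
      action[i] <- "dropped"; reason[i] <- "incompatible alleles"
    }
  }
  data.frame(rsid = common,
             beta_exp = ex$beta, se_exp = ex$se,
             beta_out = beta_out, se_out = ou$se,
             eaf_exp = ex$eaf, eaf_out = eaf_out,
             n_exp = if (!is.null(ex$n)) ex$n else NA_real_,
             n_out = if (!is.null(ou$n)) ou$n else NA_real_,
             palindromic = pal, action_taken = action, reason = reason,
             stringsAsFactors = FALSE)
}
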