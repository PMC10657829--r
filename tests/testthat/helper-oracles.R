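# Independent oracles and fixture builders shared across test files.

# Exhaustive frequent-itemset miner: enumerates every itemset up to max_size.
brute_force_itemsets <- function(transactions, min_support, max_size = 4) {
  transactions <- lapply(transactions, unique)
  n <- length(transactions)
  items <- sort(unique(unlist(transactions)))
  out <- list()
  for (k in seq_len(min(max_size, length(items)))) {
    combos <- utils::combn(items, k, simplify = FALSE)
    for (set in combos) {
      cnt <- sum(vapply(transactions, function(tr) all(set %in% tr), logical(1)))
      if (cnt / n >= min_support - 1e-9)
        out[[paste(set, collapse = "/")]] <- cnt / n
    }
  }
  out
}

# Harmonized-table constructor for estimator tests (already aligned SNPs).
make_h <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                   n_exp = 18340, n_out = 377277) {
  m <- length(beta_exp)
  data.frame(rsid = sprintf("rs%03d", seq_len(m)),
             beta_exp = beta_exp, se_exp = rep_len(se_exp, m),
             beta_out = beta_out, se_out = rep_len(se_out, m),
             eaf_exp = 0.3, eaf_out = 0.3,
             n_exp = n_exp, n_out = n_out,
             palindromic = FALSE, action_taken = "kept", reason = "",
             stringsAsFactors = FALSE)
}

# Long-format corpus with exact planted per-herb prescription frequencies.
# Occurrences are laid out in consecutive wrap-around blocks so no herb
# repeats within a prescription and every prescription is non-empty when
# sum(freqs) >= n_presc.
plant_corpus <- function(n_presc, freqs, stage = "decompensated") {
  stopifnot(all(freqs <= n_presc), sum(freqs) >= n_presc)
  offset <- 0L
  rows <- lapply(seq_along(freqs), function(i) {
    f <- freqs[i]
    presc <- ((offset + seq_len(f) - 1L) %% n_presc) + 1L
    offset <<- offset + f
    data.frame(study_id = sprintf("P%03d", presc), stage = stage,
               herb = names(freqs)[i], dose_g = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Random small transaction corpus for miner equivalence checks.
random_transactions <- function(n_items, n_trans, seed) {
  set.seed(seed)
  items <- LETTERS[seq_len(n_items)]
  lapply(seq_len(n_trans), function(i) {
    k <- sample(1:min(6, n_items), 1)
    sample(items, k)
  })
}
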