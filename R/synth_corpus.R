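#' Specification for a synthetic prescription corpus
#'
#' Describes a corpus of clinical herbal prescriptions with stage-specific
#' planted co-occurrence blocks, mimicking the structure of literature-mined
#' formula collections for compensated and decompensated cirrhosis.
#'
#' @param n_per_stage named integer vector: prescriptions per stage label,
#'   e.g. `c(compensated = 98, decompensated = 241)`.
#' @param herb_universe character vector of herb names.
#' @param core_blocks list of blocks, each
#'   `list(herbs = <character>, prob = <named numeric per stage>)`; a block's
#'   herbs are included together in a prescription of stage `s` with
#'   probability `prob[[s]]`.
#' @param background_rate per-herb independent inclusion probability for
#'   herbs outside the planted blocks.
#' @param herbs_per_prescription_range integer `c(lo, hi)`; prescriptions are
#'   padded/trimmed (background herbs only) into this range.
#' @param dose_model data.frame with columns `herb`, `mean_g`, `sd_g`, `lo_g`
#'   (truncation floor); herbs absent from it get the default row `15, 5, 3`.
#' @param seed integer root seed.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_per_stage,
                        herb_universe,
                        core_blocks = list(),
                        background_rate = 0.1,
                        herbs_per_prescription_range = c(2L, 24L),
                        dose_model = NULL,
                        seed = 1L) {
  stopifnot(length(herb_universe) > 0L, !anyDuplicated(herb_universe))
  stopifnot(all(n_per_stage >= 1), !is.null(names(n_per_stage)))
  stopifnot(background_rate >= 0, background_rate <= 1)
  r <- as.integer(herbs_per_prescription_range)
  if (!(1L <= r[1] && r[1] <= r[2] && r[2] <= length(herb_universe)))
    stop("herbs_per_prescription_range must satisfy 1 <= lo <= hi <= |herb_universe|")
  for (b in core_blocks) {
    stopifnot(all(b$herbs %in% herb_universe))
    stopifnot(all(unlist(b$prob) >= 0), all(unlist(b$prob) <= 1))
    if (length(b$herbs) > r[2])
      stop("core block larger than herbs_per_prescription_range upper bound")
  }
  structure(list(n_per_stage = n_per_stage,
                 herb_universe = herb_universe,
                 core_blocks = core_blocks,
                 background_rate = background_rate,
                 herbs_per_prescription_range = r,
                 dose_model = dose_model,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Simulate a prescription corpus
#'
#' Draws prescriptions stage by stage: each planted block enters with its
#' per-stage probability, remaining herbs enter independently at the
#' background rate, and the herb count is then forced into the configured
#' range by adding or removing background herbs (planted herbs are never
#' trimmed). Doses are drawn from per-herb normals truncated at the herb's
#' lower bound. Deterministic given the spec's seed.
#'
#' @param spec a [corpus_spec()].
#' @return A long-format data.frame with columns `study_id`, `stage`,
#'   `herb`, `dose_g` — one row per (prescription, herb).
#' @export
simulate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(child_seed(spec$seed, "corpus"), {
    rows <- vector("list", sum(spec$n_per_stage))
    k <- 0L
    rng <- spec$herbs_per_prescription_range
    dm <- spec$dose_model
    for (stage in names(spec$n_per_stage)) {
      for (i in seq_len(spec$n_per_stage[[stage]])) {
        core <- character(0)
        for (b in spec$core_blocks) {
          p <- if (is.null(names(b$prob))) b$prob[1] else (b$prob[[stage]] %||% 0)
          if (stats::runif(1) < p) core <- union(core, b$herbs)
        }
        pool <- setdiff(spec$herb_universe, core)
        bg <- pool[stats::runif(length(pool)) < spec$background_rate]
        herbs <- c(core, bg)
        if (length(herbs) < rng[1]) {
          extra <- setdiff(pool, bg)
          need <- rng[1] - length(herbs)
          herbs <- c(herbs, extra[sample.int(length(extra), need)])
        } else if (length(herbs) > rng[2]) {
          drop_n <- length(herbs) - rng[2]
          if (drop_n > length(bg))
            stop("range infeasible: planted blocks exceed upper bound")
          herbs <- c(core, bg[seq_len(length(bg) - drop_n)])
        }
        doses <- vapply(herbs, function(h) {
          if (!is.null(dm) && h %in% dm$herb) {
            j <- match(h, dm$herb)
            rnorm_trunc(1, dm$mean_g[j], dm$sd_g[j], dm$lo_g[j])
          } else rnorm_trunc(1, 15, 5, 3)
        }, numeric(1))
        k <- k + 1L
        rows[[k]] <- data.frame(
          study_id = sprintf("S%04d", k),
          stage = stage,
          herb = herbs,
          dose_g = round(doses, 1),
          stringsAsFactors = FALSE, row.names = NULL)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
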