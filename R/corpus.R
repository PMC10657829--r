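#' Read a long-format prescription table
#'
#' One row per (prescription, herb): columns `study_id`, `stage`, `herb` and
#' optionally `dose_g`. Raw herb names are canonicalized through `name_map`
#' (the Pharmacopoeia synonym dictionary); rows whose name cannot be mapped
#' and is absent from the canonical vocabulary are reported, never silently
#' dropped.
#'
#' @param path CSV file path.
#' @param name_map named character vector mapping raw synonyms to canonical
#'   herb names (`NULL` to accept names as-is).
#' @param stages allowed stage labels.
#' @return Prescription data.frame (`study_id`, `stage`, `herb`, `dose_g`).
#' @export
read_prescriptions <- function(path, name_map = NULL,
                               stages = c("compensated", "decompensated")) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty prescription file: ", path)
    return(data.frame(study_id = character(0), stage = character(0),
                      herb = character(0), dose_g = numeric(0)))
  }
  need <- c("study_id", "stage", "herb")
  if (!all(need %in% names(df)))
    stop("prescription table must have columns ", paste(need, collapse = ", "))
  if (is.null(df$dose_g)) df$dose_g <- NA_real_
  df$herb <- trimws(df$herb)
  if (!is.null(name_map)) {
    hit <- df$herb %in% names(name_map)
    df$herb[hit] <- unname(name_map[df$herb[hit]])
    unmapped <- setdiff(df$herb[!hit], unname(name_map))
    if (length(unmapped) > 0)
      warning("unmapped herb names kept verbatim: ",
              paste(sort(unique(unmapped)), collapse = ", "))
  }
  bad_stage <- setdiff(unique(df$stage), stages)
  if (length(bad_stage) > 0)
    stop("unknown stage label(s): ", paste(bad_stage, collapse = ", "))
  two_stage <- tapply(df$stage, df$study_id, function(s) length(unique(s)) > 1)
  if (any(two_stage))
    stop("study ids with conflicting stage labels: ",
         paste(names(two_stage)[two_stage], collapse = ", "))
  dup <- duplicated(df[, c("study_id", "herb")])
  if (any(dup))
    stop("duplicate (study_id, herb) rows: ",
         paste(unique(df$study_id[dup]), collapse = ", "))
  df[, c("study_id", "stage", "herb", "dose_g")]
}

#' Read an herb-attribute dictionary
#'
#' Columns: `herb`, `properties`, `flavors`, `meridians` (semicolon-delimited
#' lists) and `dose_lo_g`, `dose_hi_g` (recommended dose range in grams).
#'
#' @param path CSV file path.
#' @return data.frame with list-columns `properties`, `flavors`, `meridians`.
#' @export
read_herb_attributes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("herb", "properties", "flavors", "meridians", "dose_lo_g", "dose_hi_g")
  stopifnot(all(need %in% names(df)))
  split_field <- function(x) lapply(strsplit(x, ";", fixed = TRUE), trimws)
  df$properties <- split_field(df$properties)
  df$flavors <- split_field(df$flavors)
  df$meridians <- split_field(df$meridians)
  no_flavor <- lengths(df$flavors) == 0 | vapply(df$flavors, function(f)
    all(!nzchar(f)), logical(1))
  no_prop <- lengths(df$properties) == 0 | vapply(df$properties, function(f)
    all(!nzchar(f)), logical(1))
  if (any(no_flavor | no_prop))
    stop("herbs lacking a property or flavor: ",
         paste(df$herb[no_flavor | no_prop], collapse = ", "))
  if (any(df$dose_lo_g > df$dose_hi_g)) stop("recommended dose range inverted")
  df
}

#' Herb frequency, rate, proportion and dosage table
#'
#' For each herb in the corpus: `frequency` (number of prescriptions that
#' contain it), `rate` (percent of prescriptions), `proportion` (percent of
#' all herb occurrences), observed dose minimum / maximum / mean / sd over
#' prescriptions recording a dose, and — when an attribute dictionary is
#' supplied — whether the mean dose exceeds the recommended upper bound.
#' Percents are carried unrounded, with half-up 2-decimal print columns
#' (`rate_pct`, `proportion_pct`) alongside.
#'
#' @param prescriptions long-format prescription data.frame.
#' @param attributes optional [read_herb_attributes()] dictionary.
#' @return data.frame ordered by decreasing frequency (ties alphabetical).
#' @export
frequency_table <- function(prescriptions, attributes = NULL) {
  stopifnot(nrow(prescriptions) > 0)
  n_presc <- length(unique(prescriptions$study_id))
  total_occ <- nrow(prescriptions)
  freq <- table(prescriptions$herb)
  herbs <- names(freq)
  dose_stats <- lapply(herbs, function(h) {
    d <- prescriptions$dose_g[prescriptions$herb == h]
    d <- d[!is.na(d)]
    if (length(d) == 0) return(c(NA, NA, NA, NA))
    c(min(d), max(d), mean(d), stats::sd(d))
  })
  ds <- do.call(rbind, dose_stats)
  out <- data.frame(
    herb = herbs,
    frequency = as.integer(freq),
    rate = 100 * as.integer(freq) / n_presc,
    proportion = 100 * as.integer(freq) / total_occ,
    dose_min = ds[, 1], dose_max = ds[, 2],
    dose_mean = ds[, 3], dose_sd = ds[, 4],
    stringsAsFactors = FALSE)
  out$rate_pct <- round_half_up(out$rate, 2)
  out$proportion_pct <- round_half_up(out$proportion, 2)
  if (!is.null(attributes)) {
    j <- match(out$herb, attributes$herb)
    out$exceeds_recommended <- !is.na(j) & !is.na(out$dose_mean) &
      out$dose_mean > attributes$dose_hi_g[j]
  }
  out <- out[order(-out$frequency, out$herb), ]
  rownames(out) <- NULL
  out
}

#' Occurrence-weighted property / flavor / meridian frequencies
#'
#' Each herb contributes its prescription frequency once per attribute level
#' it carries (so a bitter-sweet herb used 40 times adds 40 to both bitter
#' and sweet). This occurrence weighting is the only counting rule consistent
#' with axis totals that exceed the number of distinct herbs.
#'
#' @param prescriptions long-format prescription data.frame.
#' @param attributes [read_herb_attributes()] dictionary.
#' @param herb_subset herbs to analyze (e.g. the high-frequency herbs); every
#'   one must have an attribute record.
#' @return data.frame `axis`, `level`, `count`, `percent` (unrounded) and
#'   `percent_pct` (half-up, 2 decimals); percents are within-axis.
#' @export
attribute_frequencies <- function(prescriptions, attributes, herb_subset) {
  missing_attr <- setdiff(herb_subset, attributes$herb)
  if (length(missing_attr) > 0)
    stop("no attribute record for: ", paste(missing_attr, collapse = ", "))
  freq <- table(prescriptions$herb)
  axes <- c(property = "properties", flavor = "flavors", meridian = "meridians")
  out <- lapply(names(axes), function(ax) {
    counts <- list()
    for (h in herb_subset) {
      f <- if (h %in% names(freq)) as.integer(freq[[h]]) else 0L
      levels_h <- attributes[[axes[[ax]]]][[match(h, attributes$herb)]]
      for (lv in levels_h[nzchar(levels_h)])
        counts[[lv]] <- (counts[[lv]] %||% 0L) + f
    }
    if (length(counts) == 0) return(NULL)
    data.frame(axis = ax, level = names(counts),
               count = unlist(counts, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$percent <- stats::ave(out$count, out$axis, FUN = function(x) 100 * x / sum(x))
  out$percent_pct <- round_half_up(out$percent, 2)
  out <- out[order(out$axis, -out$count, out$level), ]
  rownames(out) <- NULL
  out
}

#' Prescription-by-herb incidence matrix
#'
#' @param prescriptions long-format prescription data.frame.
#' @param weighted logical; `TRUE` fills doses instead of 0/1 presence.
#' @return numeric matrix, rows = prescriptions (study ids), cols = herbs,
#'   with the per-row stage labels attached as attribute `stage`.
#' @export
incidence_matrix <- function(prescriptions, weighted = FALSE) {
  ids <- unique(prescriptions$study_id)
  herbs <- sort(unique(prescriptions$herb))
  m <- matrix(0, length(ids), length(herbs), dimnames = list(ids, herbs))
  i <- match(prescriptions$study_id, ids)
  j <- match(prescriptions$herb, herbs)
  m[cbind(i, j)] <- if (weighted) ifelse(is.na(prescriptions$dose_g), 1,
                                         prescriptions$dose_g) else 1
  stage <- prescriptions$stage[match(ids, prescriptions$study_id)]
  attr(m, "stage") <- stats::setNames(stage, ids)
  m
}
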