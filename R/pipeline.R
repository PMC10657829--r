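#' Validate a pipeline run configuration
#'
#' A run configuration is a named list: `seed` (root seed), `out_dir`,
#' `stages` (subset of `corpus`, `ordination`, `rules`, `overlap`, `mr`),
#' optional per-stage parameter blocks (`rule_config`, `iv_config`,
#' `ordination`, `overlap`), and either `synthetic = TRUE` or an `inputs`
#' block of file paths. May be read from YAML via [read_run_config()].
#'
#' @param config named list.
#' @return The validated config (with defaults filled in).
#' @export
validate_run_config <- function(config) {
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||% c("corpus", "ordination", "rules",
                                        "overlap", "mr")
  config$synthetic <- isTRUE(config$synthetic)
  config$out_dir <- config$out_dir %||% stop("config field missing: out_dir")
  if (!config$synthetic) {
    if (is.null(config$inputs))
      stop("config field missing: inputs (or set synthetic: true)")
    for (f in names(config$inputs)) {
      if (!file.exists(config$inputs[[f]]))
        stop("input path does not exist for field '", f, "': ",
             config$inputs[[f]])
    }
  }
  config
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

provenance_header <- function(config, stage) {
  hash <- substr(digest_config(config), 1, 12)
  c(sprintf("# stage: %s", stage),
    sprintf("# seed: %d", config$seed),
    sprintf("# config_hash: %s", hash))
}

digest_config <- function(config) {
  # stable content hash without external digest packages; the output
  # directory is excluded so identical analyses hash identically wherever
  # they are written
  config$out_dir <- NULL
  txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

write_stage_tsv <- function(df, path, config, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, stage), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes the requested stages in dependency order over either synthetic
#' inputs (generated from the root seed) or user-supplied files, writing
#' provenance-headed TSVs under `out_dir`. Deterministic stages re-run with
#' an identical config byte-identically.
#'
#' @param config run configuration (see [validate_run_config()]).
#' @return Manifest data.frame (`stage`, `path`, `md5`), invisibly the full
#'   stage outputs as attribute `outputs`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list()
  outputs <- list()
  emit <- function(df, name, stage) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_stage_tsv(df, path, config, stage)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, path = path, md5 = unname(tools::md5sum(path)),
      stringsAsFactors = FALSE)
  }

  if (config$synthetic) {
    herbs <- sprintf("Herb%02d", 1:40)
    spec <- corpus_spec(
      n_per_stage = c(compensated = 98, decompensated = 241),
      herb_universe = herbs,
      core_blocks = list(
        list(herbs = herbs[1:3], prob = c(compensated = 0.6, decompensated = 0.2)),
        list(herbs = herbs[4:6], prob = c(compensated = 0.15, decompensated = 0.55))),
      background_rate = 0.22,
      herbs_per_prescription_range = c(2L, 24L),
      seed = child_seed(seed, "pipeline-corpus"))
    prescriptions <- simulate_corpus(spec)
    tg <- simulate_target_sets(seed = child_seed(seed, "pipeline-targets"))
    gw <- simulate_gwas(gwas_sim_spec(n_snps = 30, theta = log(1.27),
                                      exposure_beta_dist = c(0.08, 0.02),
                                      seed = child_seed(seed, "pipeline-gwas")))
  } else {
    prescriptions <- read_prescriptions(config$inputs$prescriptions)
    tg <- NULL
    gw <- NULL
  }

  if ("corpus" %in% config$stages) {
    for (st in unique(prescriptions$stage)) {
      sub <- prescriptions[prescriptions$stage == st, ]
      emit(frequency_table(sub), paste0("frequency_", st), "corpus")
    }
  }
  if ("ordination" %in% config$stages) {
    inc <- incidence_matrix(prescriptions)
    d <- bray_curtis(inc)
    ord <- pcoa(d, k = 2)
    stage_labels <- attr(inc, "stage")
    perm <- permanova(d, stage_labels, seed = child_seed(seed, "permanova"))
    coords <- data.frame(study_id = rownames(ord$coordinates),
                         stage = stage_labels,
                         ord$coordinates)
    emit(coords, "pcoa_coordinates", "ordination")
    emit(data.frame(statistic = c("pseudo_F", "p_value", "PCo1_pct", "PCo2_pct"),
                    value = c(perm$pseudo_F, perm$p_value,
                              ord$variance_explained[1:2])),
         "permanova", "ordination")
    outputs$ordination <- list(pcoa = ord, permanova = perm)
  }
  if ("rules" %in% config$stages) {
    cfg_r <- do.call(rule_config, config$rule_config %||% list())
    for (st in unique(prescriptions$stage)) {
      sub <- prescriptions[prescriptions$stage == st, ]
      mined <- mine_rules(sub, cfg_r)
      emit(mined$rules, paste0("rules_", st), "rules")
      outputs$rules[[st]] <- mined
    }
  }
  if ("overlap" %in% config$stages && !is.null(tg)) {
    ct <- cross_targets(tg$sets)
    emit(data.frame(region = names(ct$cardinality),
                    cardinality = ct$cardinality),
         "cross_target_regions", "overlap")
    hubs <- hub_ranking(tg$edges, nodes = unique(unlist(tg$sets)))
    emit(hubs, "hub_ranking", "overlap")
    outputs$overlap <- list(cross = ct, hubs = hubs)
  }
  if ("mr" %in% config$stages && !is.null(gw)) {
    cfg_iv <- do.call(iv_config, config$iv_config %||% list())
    run <- run_mr(gw$exposure, gw$outcome, gw$ld, cfg_iv,
                  exposure_name = "synthetic_taxon",
                  seed = child_seed(seed, "mr"))
    emit(mr_forest_table(list(run)), "mr_forest", "mr")
    outputs$mr <- run
  }

  man <- do.call(rbind, manifest)
  rownames(man) <- NULL
  attr(man, "outputs") <- outputs
  man
}
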