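#' Simulate three overlapping gene-target sets and a scored interaction network
#'
#' Builds herb-ingredient, microbe-metabolite and disease target sets with
#' exact planted region cardinalities (the seven regions of a three-set Venn
#' diagram), plus an undirected scored edge list in which one gene is planted
#' as the top-degree hub.
#'
#' @param n_universe size of the gene universe (symbols `G00001`, ...).
#' @param regions named integer vector of the seven exclusive Venn regions:
#'   `A`, `B`, `C` (exclusive to one set), `AB`, `AC`, `BC` (exactly two),
#'   `ABC` (all three). Missing names default to 0.
#' @param labels character vector of three set labels, in A/B/C order.
#' @param hub_degree degree of the planted hub (spokes drawn from the
#'   three-way intersection first, then the rest of the union).
#' @param n_background_edges random non-hub edges (degree kept below the
#'   hub's by construction of scores and count).
#' @param score_range range of combined scores for generated edges.
#' @param seed integer seed.
#' @return A list with `sets` (named list of gene-symbol vectors), `edges`
#'   (data.frame `gene_a`, `gene_b`, `combined_score`), and `hub`.
#' @export
simulate_target_sets <- function(n_universe = 500L,
                                 regions = c(A = 50, B = 40, C = 30,
                                             AB = 20, AC = 15, BC = 10, ABC = 85),
                                 labels = c("herb", "microbe_metabolite", "disease"),
                                 hub_degree = 10L,
                                 n_background_edges = 40L,
                                 score_range = c(0.4, 0.999),
                                 seed = 1L) {
  full <- c(A = 0, B = 0, C = 0, AB = 0, AC = 0, BC = 0, ABC = 0)
  full[names(regions)] <- regions
  if (sum(full) > n_universe)
    stop("infeasible intersection specification: regions exceed universe")
  with_seed(child_seed(seed, "targets"), {
    universe <- sprintf("G%05d", seq_len(n_universe))
    picked <- sample(universe, sum(full))
    split_idx <- rep(names(full), full)
    region_genes <- split(picked, factor(split_idx, levels = names(full)))
    A <- c(region_genes$A, region_genes$AB, region_genes$AC, region_genes$ABC)
    B <- c(region_genes$B, region_genes$AB, region_genes$BC, region_genes$ABC)
    C <- c(region_genes$C, region_genes$AC, region_genes$BC, region_genes$ABC)
    sets <- stats::setNames(list(sort(A), sort(B), sort(C)), labels)

    pool <- sort(unique(c(A, B, C)))
    hub <- if (length(region_genes$ABC) > 0) region_genes$ABC[1] else pool[1]
    spokes <- setdiff(c(region_genes$ABC, pool), hub)[seq_len(hub_degree)]
    edges <- data.frame(gene_a = hub, gene_b = spokes,
                        combined_score = stats::runif(hub_degree, score_range[1],
                                                      score_range[2]),
                        stringsAsFactors = FALSE)
    # background: sparse random edges among non-hub genes, each endpoint used
    # at most twice so the hub's degree is strictly maximal
    others <- setdiff(pool, hub)
    use_count <- stats::setNames(rep(0L, length(others)), others)
    tries <- 0L
    while (nrow(edges) - hub_degree < n_background_edges && tries < 10000L) {
      tries <- tries + 1L
      pair <- sample(others, 2)
      if (any(use_count[pair] >= 2L)) next
      if (any(edges$gene_a == pair[1] & edges$gene_b == pair[2]) ||
          any(edges$gene_a == pair[2] & edges$gene_b == pair[1])) next
      use_count[pair] <- use_count[pair] + 1L
      edges <- rbind(edges, data.frame(
        gene_a = pair[1], gene_b = pair[2],
        combined_score = stats::runif(1, score_range[1], score_range[2]),
        stringsAsFactors = FALSE))
    }
    rownames(edges) <- NULL
    list(sets = sets, edges = edges, hub = hub, universe = universe)
  })
}
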