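#' ADME screening of herbal-ingredient records
#'
#' Keeps compounds with oral bioavailability and drug-likeness at or above
#' the thresholds (boundary values kept: the screen is `>=`, not `>`).
#'
#' @param records data.frame with columns `oral_bioavailability` (percent)
#'   and `drug_likeness` (unitless in `[0, 1]`).
#' @param ob_min OB threshold (default 30 percent).
#' @param dl_min DL threshold (default 0.18).
#' @return The surviving rows.
#' @export
adme_filter <- function(records, ob_min = 30, dl_min = 0.18) {
  stopifnot(is.finite(ob_min), is.finite(dl_min))
  keep <- records$oral_bioavailability >= ob_min & records$drug_likeness >= dl_min
  records[keep & !is.na(keep), , drop = FALSE]
}

norm_genes <- function(x) unique(toupper(trimws(x[nzchar(trimws(x))])))

#' Three-way target-set intersection report
#'
#' Exact set algebra over three labeled gene sets, returning the seven
#' exclusive Venn regions (cardinalities and memberships) plus the pairwise
#' and three-way intersections — the UpSet/Venn semantics behind a
#' cross-target analysis.
#'
#' @param sets named list of three gene-symbol vectors (uppercased and
#'   whitespace-stripped on ingestion).
#' @return list: `regions` (named list of gene vectors for `A`, `B`, `C`,
#'   `AB`, `AC`, `BC`, `ABC` exclusive regions), `cardinality` (named
#'   integer), `cross_targets` (the three-way intersection), `labels`.
#' @export
cross_targets <- function(sets) {
  stopifnot(length(sets) == 3, !is.null(names(sets)))
  sets <- lapply(sets, norm_genes)
  A <- sets[[1]]; B <- sets[[2]]; C <- sets[[3]]
  regions <- list(
    A   = setdiff(A, union(B, C)),
    B   = setdiff(B, union(A, C)),
    C   = setdiff(C, union(A, B)),
    AB  = setdiff(intersect(A, B), C),
    AC  = setdiff(intersect(A, C), B),
    BC  = setdiff(intersect(B, C), A),
    ABC = intersect(intersect(A, B), C))
  list(regions = regions,
       cardinality = vapply(regions, length, integer(1)),
       cross_targets = sort(regions$ABC),
       labels = names(sets))
}

#' Degree-based hub ranking on a score-thresholded interaction network
#'
#' Edges at or above `score_cutoff` are retained; each node's degree is its
#' number of retained incident edges within `nodes`. Ranking is by degree
#' descending, ties broken lexicographically.
#'
#' @param edges data.frame `gene_a`, `gene_b`, `combined_score` in `[0, 1]`.
#' @param nodes node set to rank (e.g. the cross-target genes); `NULL` uses
#'   every node in the edge list.
#' @param score_cutoff minimum combined score (default 0.4, the usual
#'   medium-confidence interaction threshold).
#' @param top_k optionally return only the first `top_k` rows.
#' @return data.frame `gene`, `degree`, ranked.
#' @export
hub_ranking <- function(edges, nodes = NULL, score_cutoff = 0.4, top_k = NULL) {
  stopifnot(all(edges$combined_score >= 0 & edges$combined_score <= 1))
  if (any(edges$gene_a == edges$gene_b)) stop("self-loop in edge list")
  nodes <- norm_genes(nodes %||% c(edges$gene_a, edges$gene_b))
  edges <- edges[edges$combined_score >= score_cutoff, , drop = FALSE]
  a <- toupper(trimws(edges$gene_a)); b <- toupper(trimws(edges$gene_b))
  keep <- a %in% nodes & b %in% nodes
  deg <- table(factor(c(a[keep], b[keep]), levels = nodes))
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), ]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between `gene_set` and the pathway's members
#' within `universe`, Benjamini-Hochberg adjusted across tested pathways.
#'
#' @param gene_set query genes (must lie within the universe).
#' @param pathway_map named list: pathway -> member genes.
#' @param universe background gene universe; defaults to the union of all
#'   pathway members.
#' @return data.frame `pathway`, `pathway_size`, `overlap`, `p`, `q`
#'   (BH-adjusted), ordered by `p`; list-column `genes` holds the overlap.
#' @export
pathway_enrichment <- function(gene_set, pathway_map, universe = NULL) {
  stopifnot(length(pathway_map) > 0)
  pathway_map <- lapply(pathway_map, norm_genes)
  universe <- norm_genes(universe %||% unlist(pathway_map, use.names = FALSE))
  gene_set <- norm_genes(gene_set)
  outside <- setdiff(gene_set, universe)
  if (length(outside) > 0)
    stop("gene_set members outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(pathway_map), function(pw) {
    members <- intersect(pathway_map[[pw]], universe)
    if (length(members) == 0) {
      warning("pathway with no universe members skipped: ", pw)
      return(NULL)
    }
    ov <- intersect(gene_set, members)
    K <- length(members)
    p <- stats::phyper(length(ov) - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, pathway_size = K, overlap = length(ov), p = p,
               genes = I(list(sort(ov))), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable pathways")
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$pathway), c("pathway", "pathway_size", "overlap",
                                          "p", "q", "genes")]
  rownames(out) <- NULL
  out
}

#' Microbe -> metabolite -> target -> pathway linkage table
#'
#' Joins the three maps into long-format rows restricted to `core_targets`,
#' preserving row multiplicity (each join path appears once; multiplicities
#' are the natural width weights of a Sankey display). Dangling keys are
#' reported as attributes, not errors.
#'
#' @param core_targets genes the chain must pass through.
#' @param microbe_metabolite data.frame `microbe`, `metabolite`.
#' @param metabolite_target data.frame `metabolite`, `target`.
#' @param target_pathway data.frame `target`, `pathway`.
#' @return data.frame `microbe`, `metabolite`, `target`, `pathway`, with
#'   attribute `dangling` listing unjoined keys per map.
#' @export
linkage_table <- function(core_targets, microbe_metabolite, metabolite_target,
                          target_pathway) {
  core_targets <- norm_genes(core_targets)
  metabolite_target$target <- toupper(trimws(metabolite_target$target))
  target_pathway$target <- toupper(trimws(target_pathway$target))
  mt <- metabolite_target[metabolite_target$target %in% core_targets, , drop = FALSE]
  j1 <- merge(microbe_metabolite, mt, by = "metabolite")
  j2 <- merge(j1, target_pathway, by = "target")
  out <- j2[, c("microbe", "metabolite", "target", "pathway")]
  out <- out[order(out$microbe, out$metabolite, out$target, out$pathway), ]
  rownames(out) <- NULL
  attr(out, "dangling") <- list(
    metabolites = setdiff(microbe_metabolite$metabolite, metabolite_target$metabolite),
    targets = setdiff(mt$target, target_pathway$target))
  out
}

#' Read a two-column label/gene target-set file
#'
#' @param path TSV with columns `label`, `gene`.
#' @return named list of gene vectors, one per label.
#' @export
read_target_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "gene") %in% names(df)))
  lapply(split(df$gene, df$label), norm_genes)
}

#' Read a scored protein-interaction edge list
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `combined_score`.
#' @return data.frame edge list.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(df)))
  df
}

#' Read a GMT pathway file
#'
#' Standard gene-matrix-transposed format: one pathway per line —
#' name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list: pathway -> gene vector.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) norm_genes(f[-(1:2)]))
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  out
}
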