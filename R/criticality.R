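#' Normalized betweenness centrality of sub-network nodes
#'
#' Shortest-path betweenness (Brandes) on the unweighted, undirected
#' sub-network tree, endpoints excluded, normalized by (n-1)(n-2)/2 so a
#' pure chain's center scores 1. Networks with fewer than 3 nodes score 0
#' everywhere.
#'
#' @param subnet a `drug_subnetwork`, or any igraph.
#' @return named numeric vector, one value per node.
#' @export
node_betweenness <- function(subnet) {
  g <- if (inherits(subnet, "drug_subnetwork")) subnet$tree else subnet
  n <- igraph::vcount(g)
  if (n < 3) {
    return(stats::setNames(rep(0, n), igraph::V(g)$name))
  }
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  b / ((n - 1) * (n - 2) / 2)
}

#' Critical nodes at a betweenness percentile
#'
#' Nodes whose betweenness is at or above the given percentile of all node
#' scores in the sub-network (linear-interpolation percentile; ties at the
#' threshold are included).
#'
#' @param scores named numeric vector (e.g. [node_betweenness()]).
#' @param percentile percentile in (0, 100\], default 95.
#' @return character vector of node names.
#' @export
critical_nodes <- function(scores, percentile = 95) {
  if (length(scores) == 0L) stop("need at least one score")
  thr <- stats::quantile(scores, percentile / 100, type = 7, names = FALSE)
  names(scores)[scores >= thr - 1e-12]
}

#' Cross-cohort criticality table
#'
#' For every gene ever called critical, tabulates the count and percentage
#' of sub-networks in which it is critical, within the control cohort, the
#' experimental cohort, and Z-score-stratified experimental subsets
#' (Z > cut for each cut in `z_cuts`).
#'
#' @param critical_sets named list: root -> character vector of critical
#'   genes in that root's sub-network.
#' @param cohorts named character vector: root -> cohort label; must use
#'   labels `"control"` and `"experimental"`.
#' @param z_scores named numeric: Z-score per experimental root.
#' @param z_cuts Z thresholds for the stratified columns (default c(1, 2)).
#' @return data.frame with one row per gene: `<cohort>_count` and
#'   `<cohort>_pct` columns plus `z_gt_<cut>_count/_pct`; cohort sizes in
#'   the `"sizes"` attribute. Percentages are 100 * count / cohort size.
#' @export
criticality_counts <- function(critical_sets, cohorts, z_scores,
                               z_cuts = c(1, 2)) {
  stopifnot(all(names(critical_sets) %in% names(cohorts)))
  groups <- list(
    control = names(cohorts)[cohorts == "control"],
    experimental = names(cohorts)[cohorts == "experimental"]
  )
  for (cut in z_cuts) {
    groups[[paste0("z_gt_", cut)]] <-
      intersect(names(z_scores)[z_scores > cut], groups$experimental)
  }
  sizes <- vapply(groups, length, 1L)
  if (any(sizes[c("control", "experimental")] == 0L)) {
    stop("control and experimental cohorts must be non-empty")
  }
  genes <- sort(unique(unlist(critical_sets)))
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (gname in names(groups)) {
    roots <- groups[[gname]]
    cnt <- vapply(genes, function(g) {
      sum(vapply(critical_sets[roots], function(s) g %in% s, TRUE))
    }, 1L)
    tab[[paste0(gname, "_count")]] <- cnt
    tab[[paste0(gname, "_pct")]] <-
      if (length(roots)) 100 * cnt / length(roots) else NA_real_
  }
  attr(tab, "sizes") <- sizes
  tab
}

#' Genes with a large criticality spread across cohorts
#'
#' Selects rows of a criticality table whose maximum minus minimum
#' percentage across the cohort columns is at least `min_spread`
#' (boundary inclusive).
#'
#' @param table a [criticality_counts()] data.frame.
#' @param min_spread minimum spread in percentage points (default 25).
#' @return character vector of gene names.
#' @export
discrepancy_rows <- function(table, min_spread = 25) {
  pct_cols <- grep("_pct$", names(table), value = TRUE)
  spread <- apply(table[pct_cols], 1, function(r) max(r) - min(r))
  table$gene[spread >= min_spread - 1e-9]
}

#' Overlap of frequently-critical genes with an external hub list
#'
#' Genes critical in at least `min_fraction` of the chosen cohort's
#' sub-networks that are also in the supplied hub gene list (e.g. hubs of
#' an independently derived drug-specific signaling network).
#'
#' @param table a [criticality_counts()] data.frame.
#' @param hub_genes character vector of hub gene symbols.
#' @param cohort column prefix to threshold on (default `"z_gt_1"`).
#' @param min_fraction minimum fraction of cohort sub-networks (default
#'   0.25).
#' @return character vector of genes.
#' @export
hub_overlap <- function(table, hub_genes, cohort = "z_gt_1",
                        min_fraction = 0.25) {
  if (length(hub_genes) == 0L) stop("empty hub gene list")
  col <- paste0(cohort, "_pct")
  if (!col %in% names(table)) stop("no cohort column '", col, "' in table")
  frequent <- table$gene[table[[col]] >= 100 * min_fraction - 1e-9]
  intersect(frequent, hub_genes)
}
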